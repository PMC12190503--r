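# The 16-atom PhiID lattice for a two-variable lagged system.
#
# Each atom is a (source pattern -> target pattern) pair over the four PID
# patterns red, un1, un2, syn, partially ordered by red < un1 < syn,
# red < un2 < syn with un1, un2 incomparable; the atom lattice is the product
# of that order with itself.

PID_LABELS <- c("red", "un1", "un2", "syn")

# leq[a, b] is TRUE when pattern a precedes (or equals) pattern b.
pid_leq <- function() {
  leq <- matrix(FALSE, 4L, 4L, dimnames = list(PID_LABELS, PID_LABELS))
  leq["red", ] <- TRUE
  leq["un1", c("un1", "syn")] <- TRUE
  leq["un2", c("un2", "syn")] <- TRUE
  leq["syn", "syn"] <- TRUE
  leq
}

# Which variable columns of the stacked (x1 past, x2 past, x1 now, x2 now)
# covariance each single-collection pattern denotes.
SRC_COLS <- list(un1 = 1L, un2 = 2L, syn = c(1L, 2L))
TGT_COLS <- list(un1 = 3L, un2 = 4L, syn = c(3L, 4L))

.lattice_cache <- new.env(parent = emptyenv())

#' Atom lattice of the two-variable integrated information decomposition
#'
#' Enumerates the 16 (source -> target) atoms of the PhiID lattice together
#' with how each cumulative informed value is evaluated under the
#' minimum-mutual-information (MMI) redundancy function:
#' \describe{
#'   \item{`mi`}{both patterns are single variable collections; the cumulative
#'     value is a plain Gaussian mutual information (9 atoms).}
#'   \item{`red_forward`}{the source pattern is the redundancy antichain; the
#'     value is the MMI redundancy of the two past variables about the target
#'     collection (3 atoms).}
#'   \item{`red_backward`}{the target pattern is the redundancy antichain; the
#'     value is the MMI redundancy over the two present variables (3 atoms).}
#'   \item{`double_red`}{the red -> red atom, whose value is the predefined
#'     double redundancy: the minimum over all four pairwise lagged mutual
#'     informations (1 atom).}
#' }
#'
#' @return A data frame with columns `source`, `target` and `eval`, one row
#'   per atom, in the fixed source-major order used throughout the package.
#' @examples
#' lat <- phiid_lattice()
#' table(lat$eval)
#' @export
phiid_lattice <- function() {
  if (!is.null(.lattice_cache$lattice)) return(.lattice_cache$lattice)
  lat <- expand.grid(target = PID_LABELS, source = PID_LABELS,
                     stringsAsFactors = FALSE)[, c("source", "target")]
  rownames(lat) <- NULL
  lat$eval <- ifelse(
    lat$source == "red" & lat$target == "red", "double_red",
    ifelse(lat$source == "red", "red_forward",
           ifelse(lat$target == "red", "red_backward", "mi")))
  .lattice_cache$lattice <- lat
  lat
}

# 16 x 16 order relation: leq16[a, b] TRUE when atom a precedes-or-equals b.
lattice_leq <- function() {
  if (!is.null(.lattice_cache$leq16)) return(.lattice_cache$leq16)
  lat <- phiid_lattice()
  l1 <- pid_leq()
  n <- nrow(lat)
  leq16 <- matrix(FALSE, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      leq16[a, b] <- l1[lat$source[a], lat$source[b]] &&
        l1[lat$target[a], lat$target[b]]
    }
  }
  .lattice_cache$leq16 <- leq16
  leq16
}

# Indices of lattice rows in a topological (rank-increasing) order.
lattice_topo_order <- function() {
  lat <- phiid_lattice()
  rank1 <- c(red = 0L, un1 = 1L, un2 = 1L, syn = 2L)
  order(rank1[lat$source] + rank1[lat$target])
}

# Moebius coefficients: atoms = mobius %*% cumulative values.
lattice_mobius <- function() {
  if (!is.null(.lattice_cache$mobius)) return(.lattice_cache$mobius)
  leq16 <- lattice_leq()
  zeta <- t(leq16) * 1        # zeta[x, y] = 1 when y <= x
  .lattice_cache$mobius <- solve(zeta)
  .lattice_cache$mobius
}
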