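#' @useDynLib hotspotdiv, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Three-area state space used throughout: H = hotspot cells of the focal
# realm, N = non-hotspot cells of the focal realm, E = everywhere else.
# Ranges are nonempty subsets of size <= 2; the empty (null) range is an
# absorbing 7th state of the anagenetic process and never appears in data.
BIOGEO_AREAS <- c("H", "N", "E")

.STATE_SETS <- list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L))

.state_label <- function(set) paste(BIOGEO_AREAS[set], collapse = "")

#' Range states of the three-area biogeographic state space
#'
#' @return Character vector of the six non-null range states, in index order
#'   (`"H"`, `"N"`, `"E"`, `"HN"`, `"HE"`, `"NE"`).
#' @export
biogeo_states <- function() vapply(.STATE_SETS, .state_label, character(1))

.state_index <- function(labels) {
  idx <- match(labels, biogeo_states())
  if (anyNA(idx)) stop("unknown range state: ",
                       paste(labels[is.na(idx)], collapse = ", "))
  idx
}

.state_set <- function(i) .STATE_SETS[[i]]

.index_of_set <- function(set) {
  set <- sort(unique(set))
  for (i in seq_along(.STATE_SETS))
    if (identical(.STATE_SETS[[i]], set)) return(i)
  stop("no state for area set {", paste(BIOGEO_AREAS[set], collapse = ","), "}")
}

#' Anagenetic rate generator for the range-evolution CTMC
#'
#' Builds the 7x7 rate matrix over range states (six non-null ranges plus the
#' absorbing null range).  A single-area range gains a second area at rate
#' `d` per (occupied, gained) area pair; two-area ranges cannot grow (range
#' size is capped at 2).  Each occupied area is lost at rate `e`; losing the
#' only area moves the lineage to the null range.
#'
#' @param d dispersal rate (events/lineage/Ma); either a scalar (shared rate
#'   for every ordered area pair, the fitted parameterization) or a 3x3
#'   matrix of per-pair rates (used by the simulator for directional truth).
#' @param e per-area local extinction (extirpation) rate.
#' @return 7x7 rate matrix with zero row sums; rows/cols ordered as
#'   `biogeo_states()` plus `"null"`.
#' @export
anagenetic_generator <- function(d, e) {
  stopifnot(all(d >= 0), length(e) == 1L, e >= 0)
  if (length(d) == 1L) d <- matrix(d, 3, 3)
  stopifnot(identical(dim(d), c(3L, 3L)))
  diag(d) <- 0
  Q <- matrix(0, 7, 7, dimnames = rep(list(c(biogeo_states(), "null")), 2))
  for (i in 1:6) {
    r <- .state_set(i)
    if (length(r) == 1L) {
      for (b in setdiff(1:3, r))
        Q[i, .index_of_set(c(r, b))] <- sum(d[r, b])
      Q[i, 7] <- e
    } else {
      for (a in r)
        Q[i, .index_of_set(setdiff(r, a))] <- Q[i, .index_of_set(setdiff(r, a))] + e
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Cladogenetic outcome distributions for a model family
#'
#' Enumerates, for every parent range, the allowed ordered daughter-range
#' pairs with their per-family weights, normalized to a probability
#' distribution per parent.  Non-founder events carry weight 1 and founder
#' events (one daughter jumps to a single area outside the parent range,
#' allowed when `j > 0`) carry weight `j`; both daughter orders are
#' enumerated for asymmetric outcomes.
#'
#' Families differ in the non-founder outcomes they allow at a two-area
#' parent: `DEC` allows subset sympatry and narrow vicariance; `DIVALIKE`
#' allows narrow vicariance only; `BAYAREALIKE` copies the full parent range
#' to both daughters.  A single-area parent always has the sympatric copy as
#' its only non-founder outcome.
#'
#' @param family one of `"DEC"`, `"DIVALIKE"`, `"BAYAREALIKE"`.
#' @param j founder-event weight (>= 0); `0` disables founder events.
#' @return list of 6 matrices (one per parent state) with columns
#'   `left`, `right`, `prob` (states as 1-based indices).
#' @export
cladogenetic_weights <- function(family = c("DEC", "DIVALIKE", "BAYAREALIKE"),
                                 j = 0) {
  family <- match.arg(family)
  stopifnot(j >= 0)
  out <- vector("list", 6)
  for (i in 1:6) {
    r <- .state_set(i)
    ev <- list()
    add <- function(l, rr, w) ev[[length(ev) + 1L]] <<- c(l, rr, w)
    if (length(r) == 1L) {
      add(i, i, 1)
    } else {
      a <- .index_of_set(r[1]); b <- .index_of_set(r[2])
      if (family == "DEC") {
        # subset sympatry (both orders) + narrow vicariance (both orders)
        add(a, i, 1); add(b, i, 1); add(i, a, 1); add(i, b, 1)
        add(a, b, 1); add(b, a, 1)
      } else if (family == "DIVALIKE") {
        add(a, b, 1); add(b, a, 1)
      } else {
        add(i, i, 1)
      }
    }
    if (j > 0) {
      for (cc in setdiff(1:3, r)) {
        ci <- .index_of_set(cc)
        add(i, ci, j); add(ci, i, j)
      }
    }
    m <- do.call(rbind, ev)
    colnames(m) <- c("left", "right", "prob")
    m[, "prob"] <- m[, "prob"] / sum(m[, "prob"])
    out[[i]] <- m
  }
  names(out) <- biogeo_states()
  out
}

#' Classify a cladogenetic outcome
#'
#' @param parent,left,right state indices (1-based).
#' @return `"founder"` if one daughter is a single area outside the parent
#'   range, `"vicariance"` if the daughters partition a two-area parent, and
#'   `"sympatry"` otherwise (covering single-area sympatry, subset sympatry
#'   and full-range copying).
#' @export
classify_clado <- function(parent, left, right) {
  p <- .state_set(parent); l <- .state_set(left); r <- .state_set(right)
  jump_l <- length(l) == 1L && !(l %in% p)
  jump_r <- length(r) == 1L && !(r %in% p)
  if (jump_l || jump_r) return("founder")
  if (length(p) == 2L && length(intersect(l, r)) == 0L &&
      setequal(union(l, r), p)) return("vicariance")
  "sympatry"
}

#' Human-readable cladogenetic weight table for a model
#'
#' The exact normalized event table the likelihood and the stochastic mapper
#' use, with event-type labels, for inspection and documentation.
#'
#' @inheritParams cladogenetic_weights
#' @return data frame with columns `parent`, `left`, `right`, `type`, `prob`.
#' @export
describe_model <- function(family = c("DEC", "DIVALIKE", "BAYAREALIKE"), j = 0) {
  family <- match.arg(family)
  tabs <- cladogenetic_weights(family, j)
  st <- biogeo_states()
  do.call(rbind, lapply(1:6, function(i) {
    m <- tabs[[i]]
    data.frame(parent = st[i], left = st[m[, 1]], right = st[m[, 2]],
               type = vapply(seq_len(nrow(m)), function(k)
                 classify_clado(i, m[k, 1], m[k, 2]), character(1)),
               prob = m[, 3], row.names = NULL)
  }))
}
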