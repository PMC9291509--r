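#' Validity, novelty and uniqueness of generated molecules
#'
#' Validity is the fraction of chemically valid molecules among all
#' generated samples (`NA` entries count as invalid decodes).
#' Uniqueness is the fraction of generated molecules that are not
#' duplicated, by canonical SMILES.  Novelty is computed over the
#' valid-and-unique subset: the fraction of those molecules that do not
#' occur in the training set (membership by canonical SMILES).
#'
#' @param smiles character vector of generated molecules (possibly with
#'   `NA` for failed decodes).
#' @param training_set character vector of training SMILES.
#' @return a number in `[0, 1]`.
#' @export
validity_ratio <- function(smiles) {
  if (!length(smiles)) {
    stop_delfrag("validity is undefined for an empty sample",
                 "delfrag_metric_error")
  }
  ok <- !is.na(smiles) & is_valid_smiles_or_false(smiles)
  mean(ok)
}

is_valid_smiles_or_false <- function(smiles) {
  out <- logical(length(smiles))
  has <- !is.na(smiles)
  if (any(has)) out[has] <- is_valid_smiles(smiles[has])
  out
}

#' @rdname validity_ratio
#' @export
uniqueness_ratio <- function(smiles) {
  if (!length(smiles)) {
    stop_delfrag("uniqueness is undefined for an empty sample",
                 "delfrag_metric_error")
  }
  canon <- rep(NA_character_, length(smiles))
  has <- !is.na(smiles)
  canon[has] <- canonical_smiles(smiles[has])
  valid <- canon[!is.na(canon)]
  if (!length(valid)) return(0)
  length(unique(valid)) / length(smiles)
}

#' @rdname validity_ratio
#' @export
novelty_ratio <- function(smiles, training_set) {
  if (!length(smiles)) {
    stop_delfrag("novelty is undefined for an empty sample",
                 "delfrag_metric_error")
  }
  canon <- rep(NA_character_, length(smiles))
  has <- !is.na(smiles)
  canon[has] <- canonical_smiles(smiles[has])
  pool <- unique(canon[!is.na(canon)])
  if (!length(pool)) return(0)
  train <- canonical_smiles(training_set)
  mean(!(pool %in% train))
}

#' Empirical 1-Wasserstein distance on the line
#'
#' The earth-mover distance between two empirical distributions,
#' `W1 = integral of |F_a(x) - F_b(x)| dx`, computed exactly from the
#' piecewise-constant empirical CDFs (no subsampling for unequal sizes).
#' For equal sample sizes this equals the mean absolute difference of the
#' sorted samples.
#'
#' @param a,b numeric vectors (finite, non-empty).
#' @return non-negative scalar; 0 iff the empirical distributions match.
#' @export
wasserstein1 <- function(a, b) {
  if (!length(a) || !length(b)) {
    stop_delfrag("Wasserstein distance needs non-empty samples",
                 "delfrag_metric_error")
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop_delfrag("Wasserstein distance needs finite samples",
                 "delfrag_metric_error")
  }
  xs <- sort(unique(c(a, b)))
  if (length(xs) == 1) return(0)
  Fa <- stats::ecdf(a)(xs)
  Fb <- stats::ecdf(b)(xs)
  k <- seq_len(length(xs) - 1)
  sum(abs(Fa[k] - Fb[k]) * diff(xs))
}

#' Hypervolume dominated by a Pareto front (minimization)
#'
#' Lebesgue measure of the union of the axis-aligned boxes spanned by
#' each front point and the reference point.  Every front point must
#' weakly dominate the reference point.  Dimensions 2 and 3 are computed
#' by an exact sweep; higher dimensions recurse by slicing on the last
#' objective.
#'
#' @param front numeric matrix (rows are points) or a single point.
#' @param ref numeric reference point, componentwise no better than any
#'   front point.
#' @return non-negative scalar.
#' @export
hypervolume <- function(front, ref) {
  front <- if (is.null(dim(front))) matrix(front, nrow = 1) else as.matrix(front)
  ref <- as.numeric(ref)
  if (ncol(front) != length(ref)) {
    stop_delfrag("reference point dimension mismatch", "delfrag_shape_error")
  }
  if (nrow(front) == 0) return(0)
  if (any(front > matrix(ref, nrow(front), length(ref), byrow = TRUE))) {
    stop_delfrag("a front point lies beyond the reference point",
                 "delfrag_invalid_reference")
  }
  hv_rec(front, ref)
}

hv_rec <- function(P, ref) {
  d <- length(ref)
  if (d == 1) return(ref - min(P[, 1]))
  if (d == 2) return(hv_2d(P, ref))
  ord <- order(P[, d])
  P <- P[ord, , drop = FALSE]
  z <- P[, d]
  total <- 0
  n <- nrow(P)
  for (k in seq_len(n)) {
    z_hi <- if (k < n) z[k + 1] else ref[d]
    slab <- z_hi - z[k]
    if (slab > 0) {
      sub <- P[seq_len(k), -d, drop = FALSE]
      total <- total + slab * hv_rec(sub, ref[-d])
    }
  }
  total
}

hv_2d <- function(P, ref) {
  ord <- order(P[, 1], P[, 2])
  P <- P[ord, , drop = FALSE]
  area <- 0
  y_prev <- ref[2]
  for (k in seq_len(nrow(P))) {
    if (P[k, 2] < y_prev) {
      area <- area + (ref[1] - P[k, 1]) * (y_prev - P[k, 2])
      y_prev <- P[k, 2]
    }
  }
  area
}

# fixed reference point for a run: componentwise max of the initial
# population's objectives plus a 10% margin (margin floor of 0.1 so that
# values near zero, and negative binding scores, still get headroom)
hv_reference_point <- function(members) {
  objs <- as.matrix(members[, c("sas", "logp", "bas")])
  objs <- objs[apply(is.finite(objs), 1, all), , drop = FALSE]
  m <- apply(objs, 2, max)
  m + 0.1 * pmax(abs(m), 1)
}

#' Per-generation quality report
#'
#' One metrics row for a population: validity, novelty and uniqueness of
#' the generation's raw decoder output, the 1-Wasserstein distance of
#' each objective's distribution to the initial data, and the
#' hypervolume of the first front under the run's fixed reference point
#' (front points beyond the reference point are clipped out).
#'
#' @param pop a `del_population` (evaluated).
#' @param initial_records data.frame of the initial population with
#'   `sas`, `logp`, `bas` columns.
#' @param ref numeric length-3 reference point.
#' @param training_set character vector of training SMILES (for novelty).
#' @return one-row data.frame.
#' @export
generation_report <- function(pop, initial_records, ref, training_set) {
  m <- pop$members
  generated <- if (!is.null(pop$generated)) pop$generated else m$smiles
  front <- as.matrix(m[!is.na(m$rank) & m$rank == 1, c("sas", "logp", "bas")])
  front <- front[apply(front <= matrix(ref, nrow(front), 3, byrow = TRUE), 1, all),
                 , drop = FALSE]
  data.frame(
    generation = pop$generation,
    validity = validity_ratio(generated),
    novelty = novelty_ratio(generated, training_set),
    uniqueness = uniqueness_ratio(generated),
    w1_sas = wasserstein1(m$sas, initial_records$sas),
    w1_logp = wasserstein1(m$logp, initial_records$logp),
    w1_bas = wasserstein1(m$bas[is.finite(m$bas)],
                          initial_records$bas[is.finite(initial_records$bas)]),
    hypervolume = if (nrow(front)) hypervolume(front, ref) else 0,
    front1_size = nrow(front)
  )
}
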