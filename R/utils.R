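#' @keywords internal
sigmoid <- function(x) stats::plogis(x)

#' Derive deterministic sub-seeds from one master seed
#'
#' All randomness in the package flows from a single integer master seed.
#' Independent consumers (per-site feature draws, label draws, fold plans,
#' forest seeds) receive sub-seeds drawn once from the master stream, so
#' adding a consumer never perturbs the draws of another run with the same
#' seed and fewer consumers is avoided by always drawing a fixed-size block.
#'
#' @param seed integer master seed.
#' @param n number of sub-seeds to derive.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Stratified assignment of rows to k folds. Within each class, rows are
# shuffled and dealt round-robin from a random starting fold, so per-fold
# class counts differ by at most one sample from an exactly proportional
# allocation. Falls back to non-stratified dealing (with a warning) when a
# class has fewer members than folds and `strict = FALSE`.
#' @keywords internal
stratified_fold_ids <- function(labels, k, seed, strict = FALSE) {
  stopifnot(k >= 2L)
  n <- length(labels)
  ids <- integer(n)
  set.seed(as.integer(seed))
  classes <- sort(unique(labels))
  if (any(tabulate(factor(labels, levels = classes)) < k)) {
    if (strict) stop("each class needs at least k = ", k, " members")
    warning("a class has fewer than k members; falling back to non-stratified folds")
    perm <- sample.int(n)
    ids[perm] <- rep_len(sample.int(k), n)
    return(ids)
  }
  for (cl in classes) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    start <- sample.int(k, 1L)
    ids[idx] <- ((start - 1L + seq_along(idx) - 1L) %% k) + 1L
  }
  ids
}
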