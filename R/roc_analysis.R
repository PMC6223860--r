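#' Nonparametric (Mann-Whitney) AUC
#'
#' Fraction of (absent, present) score pairs with present > absent, counting
#' ties as 1/2 — identical to the trapezoidal area under the empirical ROC
#' curve. Computed via midranks, which matches an exhaustive double-loop pair
#' count exactly, ties included.
#'
#' @param scores_absent numeric scores of the signal-absent class.
#' @param scores_present numeric scores of the signal-present class.
#' @return the AUC in `[0, 1]`.
#' @examples
#' auc_mann_whitney(c(0, 1), c(0.5, 2))  # 0.75
#' @export
auc_mann_whitney <- function(scores_absent, scores_present) {
  a <- as.numeric(scores_absent); p <- as.numeric(scores_present)
  if (length(a) == 0L || length(p) == 0L)
    stop("both score classes must be non-empty", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(p)))
    stop("scores must be finite", call. = FALSE)
  n0 <- length(a); n1 <- length(p)
  r <- rank(c(a, p), ties.method = "average")
  (sum(r[(n0 + 1):(n0 + n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Bootstrap AUC with mean and standard deviation
#'
#' Resamples each class independently with replacement at its own size,
#' recomputes the Mann-Whitney AUC for each of `n_boot` replicates (default
#' 500), and reports the replicate mean and SD alongside the point estimate on
#' the original scores. Fully reproducible given `seed`; the caller's RNG
#' state is untouched.
#'
#' @param scores_absent signal-absent scores (length >= 2).
#' @param scores_present signal-present scores (length >= 2).
#' @param n_boot number of bootstrap replicates (>= 1; default 500).
#' @param seed integer RNG seed.
#' @param ci_level optional level for a percentile interval (e.g. 0.95);
#'   `NULL` (default) skips it.
#' @return an object of class `auc_result`: list with `auc_point`, `auc_mean`,
#'   `auc_sd`, `n_boot`, `seed`, `n_absent`, `n_present`, and `ci` when
#'   requested.
#' @export
bootstrap_auc <- function(scores_absent, scores_present, n_boot = 500L,
                          seed = 1L, ci_level = NULL) {
  a <- as.numeric(scores_absent); p <- as.numeric(scores_present)
  if (length(a) < 2L || length(p) < 2L)
    stop("each class needs at least 2 scores for the bootstrap", call. = FALSE)
  stopifnot_scalar_num(n_boot, "n_boot", integer = TRUE)
  if (n_boot < 1L) stop("`n_boot` must be >= 1", call. = FALSE)
  stopifnot_scalar_num(seed, "seed", integer = TRUE)
  point <- auc_mann_whitney(a, p)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      auc_mann_whitney(a[sample.int(length(a), replace = TRUE)],
                       p[sample.int(length(p), replace = TRUE)])
    }, numeric(1))
  })
  res <- structure(list(
    auc_point = point,
    auc_mean = mean(reps),
    auc_sd = if (n_boot > 1L) sd(reps) else 0,
    n_boot = as.integer(n_boot),
    seed = as.integer(seed),
    n_absent = length(a),
    n_present = length(p)
  ), class = "auc_result")
  if (!is.null(ci_level)) {
    stopifnot_scalar_num(ci_level, "ci_level", positive = TRUE)
    alpha <- (1 - ci_level) / 2
    res$ci <- unname(quantile(reps, c(alpha, 1 - alpha), type = 7))
  }
  res
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.4f (bootstrap mean %.4f, SD %.4f; %d replicates, %d/%d scores)\n",
              x$auc_point, x$auc_mean, x$auc_sd, x$n_boot, x$n_absent, x$n_present))
  invisible(x)
}

#' Read and write score sets as CSV
#'
#' A score set is stored as two columns, `label` (`signal_absent` /
#' `signal_present`) and `score`, so model scoring and ROC analysis can run as
#' separate steps.
#'
#' @param scores a `score_set` from [decision_variables()].
#' @param path CSV path.
#' @return `write_score_set` returns `path` invisibly; `read_score_set`
#'   returns a `score_set`.
#' @export
write_score_set <- function(scores, path) {
  stopifnot(inherits(scores, "score_set"))
  df <- data.frame(
    label = rep(c("signal_absent", "signal_present"),
                c(length(scores$lambda_absent), length(scores$lambda_present))),
    score = c(scores$lambda_absent, scores$lambda_present)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_set
#' @export
read_score_set <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "score") %in% names(df)))
    stop("score CSV must have columns `label` and `score`", call. = FALSE)
  structure(list(lambda_absent = df$score[df$label == "signal_absent"],
                 lambda_present = df$score[df$label == "signal_present"]),
            class = "score_set")
}
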