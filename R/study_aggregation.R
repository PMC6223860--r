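#' Distribution summary in the multicentre-figure convention
#'
#' Median, quartiles and 5th/95th percentiles by linear interpolation between
#' order statistics (R's type-7 quantile rule), with "outliers" defined as
#' values outside the 5th-95th percentile band — the convention of the study's
#' box-style dose and AUC figures.
#'
#' @param values numeric vector (n >= 1).
#' @param ids optional identifiers (e.g. centre ids) aligned with `values`.
#' @return an object of class `distribution_summary`: list with `n`, `median`,
#'   `q1`, `q3`, `p5`, `p95`, and `outliers` (data frame of id, value).
#' @examples
#' summarize_distribution(1:10)  # q1 = 3.25, q3 = 7.75
#' @export
summarize_distribution <- function(values, ids = NULL) {
  v <- as.numeric(values)
  if (length(v) == 0L) stop("`values` must be non-empty", call. = FALSE)
  if (!all(is.finite(v))) stop("`values` must be finite", call. = FALSE)
  if (is.null(ids)) ids <- as.character(seq_along(v))
  if (length(ids) != length(v))
    stop("`ids` must align with `values`", call. = FALSE)
  q <- unname(quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7))
  out <- v < q[1] | v > q[5]
  structure(list(n = length(v), median = q[3], q1 = q[2], q3 = q[4],
                 p5 = q[1], p95 = q[5],
                 outliers = data.frame(id = as.character(ids)[out],
                                       value = v[out],
                                       stringsAsFactors = FALSE)),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("n=%d  median %.3g [q1 %.3g, q3 %.3g] (p5 %.3g, p95 %.3g), %d outlier(s)\n",
              x$n, x$median, x$q1, x$q3, x$p5, x$p95, nrow(x$outliers)))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length n >= 3, neither constant.
#' @return r in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("correlation needs n >= 3", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation is undefined for a constant input", call. = FALSE)
  cor(x, y)
}

#' Qualitative correlation-strength label (Evans scale)
#'
#' Maps |r| to the five-category verbal scale: `[0, 0.20)` very weak,
#' `[0.20, 0.40)` weak, `[0.40, 0.60)` moderate, `[0.60, 0.80)` strong,
#' `[0.80, 1]` very strong.
#'
#' @param r correlation coefficient(s) in `[-1, 1]` (vectorised).
#' @return character vector of labels.
#' @examples
#' evans_label(c(0.39, 0.49, -0.85))
#' @export
evans_label <- function(r) {
  r <- as.numeric(r)
  if (any(!is.finite(r)) || any(abs(r) > 1))
    stop("`r` must lie in [-1, 1]", call. = FALSE)
  labs <- c("very weak", "weak", "moderate", "strong", "very strong")
  labs[pmin(findInterval(abs(r), c(0, 0.2, 0.4, 0.6, 0.8)), 5L)]
}

#' Build a study-record table
#'
#' One row per centre x phantom size: scanner identity, ATCM type, displayed
#' CTDIvol and the AUC summary. This is the input of all aggregation
#' operations and matches the records CSV layout.
#'
#' @param centre_id,scanner_model,manufacturer character vectors.
#' @param atcm_type `"noise_level"`, `"reference_mAs"` or `"unknown"` — the
#'   two automatic tube-current-modulation families (target noise level
#'   vs. reference image load in mAs).
#' @param phantom_size `"S"`, `"M"` or `"L"`.
#' @param ctdi_vol_mgy displayed CTDIvol in mGy (> 0).
#' @param auc_mean,auc_sd bootstrap AUC summary per record.
#' @return a data frame of class `study_records`.
#' @export
study_records <- function(centre_id, scanner_model = "", manufacturer = "",
                          atcm_type = "unknown", phantom_size, ctdi_vol_mgy,
                          auc_mean, auc_sd = NA_real_) {
  df <- data.frame(centre_id = as.character(centre_id),
                   scanner_model = as.character(scanner_model),
                   manufacturer = as.character(manufacturer),
                   atcm_type = as.character(atcm_type),
                   phantom_size = as.character(phantom_size),
                   ctdi_vol_mgy = as.numeric(ctdi_vol_mgy),
                   auc_mean = as.numeric(auc_mean),
                   auc_sd = as.numeric(auc_sd),
                   stringsAsFactors = FALSE)
  if (!all(df$phantom_size %in% c("S", "M", "L")))
    stop("`phantom_size` must be one of S, M, L", call. = FALSE)
  if (!all(df$atcm_type %in% c("noise_level", "reference_mAs", "unknown")))
    stop("`atcm_type` must be noise_level, reference_mAs or unknown", call. = FALSE)
  if (any(!is.finite(df$ctdi_vol_mgy)) || any(df$ctdi_vol_mgy <= 0))
    stop("`ctdi_vol_mgy` must be positive", call. = FALSE)
  if (any(df$auc_mean < 0 | df$auc_mean > 1, na.rm = TRUE))
    stop("`auc_mean` must lie in [0, 1]", call. = FALSE)
  class(df) <- c("study_records", "data.frame")
  df
}

#' Cross-size AUC correlation matrix
#'
#' Pearson correlation of per-centre AUC between phantom-size pairs over
#' {S, M, L}: unit diagonal, symmetric, pairwise-complete (only centres
#' measured at both sizes of a pair enter that pair's r). Cells with fewer
#' than 3 complete pairs, or with a constant margin, are undefined and
#' returned as NA.
#'
#' @param records a [study_records()] data frame (at most one AUC per centre
#'   per size).
#' @param atcm optional ATCM stratum to filter on before correlating.
#' @return a 3 x 3 symmetric matrix with dimnames S/M/L.
#' @export
correlation_matrix <- function(records, atcm = NULL) {
  stopifnot(is.data.frame(records))
  if (!is.null(atcm)) records <- records[records$atcm_type == atcm, , drop = FALSE]
  sizes <- c("S", "M", "L")
  if (any(duplicated(records[c("centre_id", "phantom_size")])))
    stop("each centre may contribute at most one AUC per phantom size", call. = FALSE)
  # centre x size AUC table
  centres <- unique(records$centre_id)
  wide <- vapply(sizes, function(s) {
    sub <- records[records$phantom_size == s, ]
    sub$auc_mean[match(centres, sub$centre_id)]
  }, numeric(length(centres)))
  wide <- matrix(wide, nrow = length(centres), ncol = 3L)
  m <- diag(1, 3)
  dimnames(m) <- list(sizes, sizes)
  for (i in 1:2) for (j in (i + 1):3) {
    ok <- is.finite(wide[, i]) & is.finite(wide[, j])
    r <- if (sum(ok) < 3L) NA_real_ else {
      xi <- wide[ok, i]; xj <- wide[ok, j]
      if (sd(xi) == 0 || sd(xj) == 0) NA_real_ else cor(xi, xj)
    }
    m[i, j] <- m[j, i] <- r
  }
  m
}

#' Assemble the study-level report
#'
#' For each phantom size, summarises the CTDIvol and AUC distributions
#' ([summarize_distribution()]); computes the cross-size AUC correlation
#' matrix overall and per ATCM stratum, with Evans labels. Deterministic for
#' a given record table.
#'
#' @param records a [study_records()] data frame.
#' @return a list of class `study_report`: `dose` and `auc` (data frames of
#'   per-size summaries), `correlations` (named list of matrices:
#'   `overall` plus one per ATCM stratum present), and `evans` (data frame of
#'   pairwise labels).
#' @export
build_report <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("`records` must contain at least one row", call. = FALSE)
  sizes <- c("S", "M", "L")
  summarise_by_size <- function(col) {
    do.call(rbind, lapply(sizes, function(s) {
      sub <- records[records$phantom_size == s, ]
      if (nrow(sub) == 0L)
        return(data.frame(phantom_size = s, n = 0L, median = NA_real_,
                          q1 = NA_real_, q3 = NA_real_, p5 = NA_real_,
                          p95 = NA_real_, n_outliers = NA_integer_))
      d <- summarize_distribution(sub[[col]], sub$centre_id)
      data.frame(phantom_size = s, n = d$n, median = d$median, q1 = d$q1,
                 q3 = d$q3, p5 = d$p5, p95 = d$p95,
                 n_outliers = nrow(d$outliers))
    }))
  }
  strata <- intersect(c("noise_level", "reference_mAs"), unique(records$atcm_type))
  cors <- c(list(overall = correlation_matrix(records)),
            stats::setNames(lapply(strata, correlation_matrix, records = records),
                            strata))
  pairs <- t(utils::combn(sizes, 2))
  evans <- do.call(rbind, lapply(names(cors), function(stratum) {
    m <- cors[[stratum]]
    data.frame(stratum = stratum, size_a = pairs[, 1], size_b = pairs[, 2],
               r = m[cbind(pairs[, 1], pairs[, 2])],
               label = ifelse(is.na(m[cbind(pairs[, 1], pairs[, 2])]),
                              NA_character_,
                              evans_label(ifelse(is.na(m[cbind(pairs[, 1], pairs[, 2])]),
                                                 0, m[cbind(pairs[, 1], pairs[, 2])]))),
               stringsAsFactors = FALSE)
  }))
  structure(list(dose = summarise_by_size("ctdi_vol_mgy"),
                 auc = summarise_by_size("auc_mean"),
                 correlations = cors, evans = evans),
            class = "study_report")
}

#' Write a study report as CSV files
#'
#' @param report a `study_report` from [build_report()].
#' @param dir output directory (created if needed). Writes `dose_summary.csv`,
#'   `auc_summary.csv`, `correlations.csv` (long form) and `evans_labels.csv`.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$dose, file.path(dir, "dose_summary.csv"), row.names = FALSE)
  write.csv(report$auc, file.path(dir, "auc_summary.csv"), row.names = FALSE)
  long <- do.call(rbind, lapply(names(report$correlations), function(s) {
    m <- report$correlations[[s]]
    data.frame(stratum = s,
               size_a = rep(rownames(m), times = 3),
               size_b = rep(colnames(m), each = 3),
               r = as.numeric(m), stringsAsFactors = FALSE)
  }))
  write.csv(long, file.path(dir, "correlations.csv"), row.names = FALSE)
  write.csv(report$evans, file.path(dir, "evans_labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read study records from CSV
#'
#' Columns: centre_id, manufacturer, scanner_model, atcm_type, phantom_size,
#' ctdi_vol_mgy, auc_mean, auc_sd.
#'
#' @param path CSV path.
#' @return a [study_records()] data frame.
#' @export
read_study_records <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("centre_id", "phantom_size", "ctdi_vol_mgy", "auc_mean")
  if (!all(need %in% names(df)))
    stop(sprintf("records CSV must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  study_records(centre_id = df$centre_id,
                scanner_model = if ("scanner_model" %in% names(df)) df$scanner_model else "",
                manufacturer = if ("manufacturer" %in% names(df)) df$manufacturer else "",
                atcm_type = if ("atcm_type" %in% names(df)) df$atcm_type else "unknown",
                phantom_size = df$phantom_size,
                ctdi_vol_mgy = df$ctdi_vol_mgy,
                auc_mean = df$auc_mean,
                auc_sd = if ("auc_sd" %in% names(df)) df$auc_sd else NA_real_)
}

# Pearson correlation between pnorm(a1 + b1 Z1) and pnorm(a2 + b2 Z2) for
# latent correlation rho, via the closed 1-D reduction
# E[A2 | Z1 = z] = pnorm((a2 + b2 rho z) / sqrt(1 + b2^2 (1 - rho^2))).
probit_pair_cor <- function(a1, b1, a2, b2, rho) {
  moment <- function(r) {
    stats::integrate(function(z)
      stats::dnorm(z) * pnorm(a1 + b1 * z) *
        pnorm((a2 + b2 * r * z) / sqrt(1 + b2^2 * (1 - r^2))),
      -Inf, Inf, rel.tol = 1e-10)$value
  }
  m1 <- pnorm(a1 / sqrt(1 + b1^2)); m2 <- pnorm(a2 / sqrt(1 + b2^2))
  v1 <- stats::integrate(function(z)
    stats::dnorm(z) * pnorm(a1 + b1 * z)^2, -Inf, Inf, rel.tol = 1e-10)$value - m1^2
  v2 <- stats::integrate(function(z)
    stats::dnorm(z) * pnorm(a2 + b2 * z)^2, -Inf, Inf, rel.tol = 1e-10)$value - m2^2
  (moment(rho) - m1 * m2) / sqrt(v1 * v2)
}

# Latent Gaussian correlation needed so the probit-transformed pair attains
# the target Pearson correlation (NORTA-style pre-compensation).
probit_latent_rho <- function(a1, b1, a2, b2, target) {
  if (target == 0) return(0)
  stats::uniroot(function(r) probit_pair_cor(a1, b1, a2, b2, r) - target,
                 interval = c(0, 0.9999), tol = 1e-8)$root
}

#' Simulate a multicentre cohort with known cross-size correlation
#'
#' Generates per-centre AUC values for the three phantom sizes from a latent
#' Gaussian mapped through a probit link so the values stay in (0, 1) around
#' size-specific typical levels, plus log-normal CTDIvol draws around
#' size-specific medians. The latent Gaussian correlations are
#' pre-compensated (NORTA construction) so that the Pearson correlation of
#' the generated AUC values themselves equals `latent_r` for every size pair
#' in expectation — the ground truth the aggregation statistics are validated
#' against. The generator does not model scanner physics.
#'
#' @param n_centres number of centres (default 68).
#' @param latent_r latent cross-size correlation in `[0, 1)` (default 0.5).
#' @param seed integer RNG seed.
#' @param auc_levels typical AUC per size (probit-space means derive from
#'   these; defaults 0.96 / 0.90 / 0.83 for S/M/L).
#' @param ctdi_medians median CTDIvol per size, mGy (defaults 5.8 / 10.5 /
#'   16.3).
#' @param atcm_split fraction of centres on the noise-level ATCM family
#'   (default 0.5).
#' @return a [study_records()] data frame with 3 rows per centre.
#' @export
simulate_study_records <- function(n_centres = 68L, latent_r = 0.5, seed = 1L,
                                   auc_levels = c(S = 0.96, M = 0.90, L = 0.83),
                                   ctdi_medians = c(S = 5.8, M = 10.5, L = 16.3),
                                   atcm_split = 0.5) {
  stopifnot_scalar_num(n_centres, "n_centres", positive = TRUE, integer = TRUE)
  stopifnot_scalar_num(latent_r, "latent_r")
  if (latent_r < 0 || latent_r >= 1)
    stop("`latent_r` must lie in [0, 1)", call. = FALSE)
  mu <- qnorm(auc_levels)
  b <- 0.35                                    # probit-scale spread
  # pre-compensate the latent correlations so the AUC-scale Pearson r hits
  # latent_r for every pair despite the probit nonlinearity
  R <- diag(1, 3)
  for (i in 1:2) for (j in (i + 1):3)
    R[i, j] <- R[j, i] <- probit_latent_rho(mu[i], b, mu[j], b, latent_r)
  L <- chol(R)
  with_seed(seed, {
    z <- matrix(rnorm(n_centres * 3), n_centres, 3) %*% L
    auc <- pnorm(sweep(z * b, 2, mu, `+`))
    ctdi <- sapply(ctdi_medians, function(m) m * exp(rnorm(n_centres, sd = 0.35)))
    atcm <- ifelse(runif(n_centres) < atcm_split, "noise_level", "reference_mAs")
    study_records(
      centre_id = rep(sprintf("centre%03d", seq_len(n_centres)), times = 3),
      scanner_model = "synthetic",
      manufacturer = "synthetic",
      atcm_type = rep(atcm, times = 3),
      phantom_size = rep(c("S", "M", "L"), each = n_centres),
      ctdi_vol_mgy = as.numeric(ctdi),
      auc_mean = as.numeric(auc),
      auc_sd = 0.02
    )
  })
}
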