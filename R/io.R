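#' Read a summary-statistics table
#'
#' Reads a tab-separated table with header columns `snp`, `beta_exposure`,
#' `se_exposure`, `beta_outcome`, `se_outcome` (extra columns ignored; plain
#' or scientific notation). If a standard-error column is absent it can be
#' recovered from a matching p-value column (`pval_exposure` /
#' `pval_outcome`) as \eqn{|\hat\beta| / \Phi^{-1}(1 - p/2)}, the inversion
#' of a two-sided normal test.
#'
#' Rows containing missing or non-finite values are dropped with a warning
#' naming each rejected row; zero or negative standard errors and zero
#' SNP-exposure estimates are errors.
#'
#' @param path file path.
#' @return an [mr_summary] dataset.
#' @export
read_summary_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need_beta <- c("beta_exposure", "beta_outcome")
  missing_beta <- setdiff(need_beta, names(tab))
  if (length(missing_beta))
    stop("missing required column(s): ", paste(missing_beta, collapse = ", "))
  for (side in c("exposure", "outcome")) {
    se_col <- paste0("se_", side)
    if (!se_col %in% names(tab)) {
      p_col <- paste0("pval_", side)
      if (!p_col %in% names(tab))
        stop(sprintf("missing column '%s' and no '%s' to recover it from",
                     se_col, p_col))
      b <- tab[[paste0("beta_", side)]]
      tab[[se_col]] <- abs(b) / stats::qnorm(1 - tab[[p_col]] / 2)
      message(sprintf("recovered %s from %s via |beta|/qnorm(1 - p/2)",
                      se_col, p_col))
    }
  }
  cols <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  vals <- tab[, cols]
  ok <- apply(vals, 1L, function(r) all(is.finite(r)))
  if (any(!ok)) {
    warning(sprintf("dropped %d row(s) with missing/non-finite values: %s",
                    sum(!ok), paste(which(!ok), collapse = ", ")))
    tab <- tab[ok, , drop = FALSE]
  }
  if (nrow(tab) == 0L) stop("no usable rows in ", path)
  if (any(tab$se_exposure <= 0) || any(tab$se_outcome <= 0))
    stop("zero or negative standard errors in ", path)
  if (any(tab$beta_exposure == 0))
    stop("zero SNP-exposure estimate (cannot form ratio) in rows: ",
         paste(which(tab$beta_exposure == 0), collapse = ", "))
  snp <- if ("snp" %in% names(tab)) as.character(tab$snp) else NULL
  mr_summary(beta_exposure = tab$beta_exposure,
             se_exposure = tab$se_exposure,
             beta_outcome = tab$beta_outcome,
             se_outcome = tab$se_outcome,
             snp = snp)
}

#' Write a summary-statistics table
#'
#' Tab-separated UTF-8 with a one-line header and 17 significant digits, so
#' a write/read round trip reproduces every double exactly.
#'
#' @param data an [mr_summary] dataset.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(data, path) {
  stopifnot(inherits(data, "mr_summary"))
  out <- data.frame(
    snp = data$snp,
    beta_exposure = sprintf("%.17g", data$beta_exposure),
    se_exposure = sprintf("%.17g", data$se_exposure),
    beta_outcome = sprintf("%.17g", data$beta_outcome),
    se_outcome = sprintf("%.17g", data$se_outcome),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write estimator results with a reproducibility sidecar
#'
#' Writes per-method results as a tab-separated table (`method`, `beta`,
#' `se`, `ci_low`, `ci_high`, `p`) plus a JSON sidecar (`<path>.json`)
#' holding the settings and the dataset diagnostics (Cochran's Q, mean F,
#' F attenuation, I2GX), sufficient to re-run the analysis identically.
#'
#' @param estimates list of `causal_estimate` objects.
#' @param path output TSV path.
#' @param data the [mr_summary] dataset the estimates came from (for the
#'   diagnostics block); optional.
#' @param settings list echoed into the sidecar (seeds, CLI options, ...).
#' @return `path`, invisibly.
#' @export
write_mr_results <- function(estimates, path, data = NULL,
                             settings = list()) {
  tab <- do.call(rbind, lapply(estimates, as.data.frame))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  sidecar <- list(package = "modemr",
                  version = as.character(utils::packageVersion("modemr")),
                  settings = settings)
  if (!is.null(data)) {
    q <- cochran_q(data)
    st <- instrument_strength(data)
    sidecar$diagnostics <- list(
      L = nrow(data), q = q$q, q_df = q$df, q_p_value = q$p_value,
      mean_f = st$mean_f, f_attenuation = st$f_attenuation,
      igx2 = st$igx2, igx2_floored = st$igx2_floored)
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Generate a synthetic summary-data fixture
#'
#' Builds small synthetic datasets with a known validity structure, for
#' testing and demonstration. The exposure side has strong instruments
#' (`beta_exposure ~ U(0.1, 0.3)` with small SEs); the outcome side is
#' `beta * beta_exposure + alpha_j` plus noise, where the per-variant
#' pleiotropic effect `alpha_j` (hence the bias `b_j = alpha_j /
#' beta_exposure_j`) depends on `kind`:
#' * `all_valid` -- every `alpha_j = 0`.
#' * `zempa_ok` -- most instruments invalid but each with a distinct large
#'   bias; the valid minority still forms the tallest density peak, so the
#'   zero-modal-pleiotropy assumption holds.
#' * `zempa_violated` -- a cluster of invalid instruments shares one bias
#'   value and outnumbers the valid set, so the modal bias is nonzero and
#'   the mode-based estimate is pulled to the shared biased value.
#' * `inside_violated` -- pleiotropic effects proportional to instrument
#'   strength (violating InSIDE, biasing MR-Egger).
#'
#' When `path` is given, writes the summary table there and a JSON truth
#' sidecar (`<path>.json`) with the true causal effect and per-variant
#' biases.
#'
#' @param kind fixture kind.
#' @param L number of variants (>= 8).
#' @param seed integer seed.
#' @param beta true causal effect.
#' @param path optional output TSV path.
#' @return the [mr_summary] dataset, with attributes `truth_beta`, `bias`
#'   and `valid`.
#' @export
generate_fixture <- function(kind = c("all_valid", "zempa_ok",
                                      "zempa_violated", "inside_violated"),
                             L = 30, seed = 1, beta = 0.3, path = NULL) {
  kind <- match.arg(kind)
  stopifnot(L >= 8)
  set.seed(seed)
  bx <- stats::runif(L, 0.1, 0.3)
  sx <- stats::runif(L, 0.008, 0.015)
  sy <- stats::runif(L, 0.008, 0.015)
  bias <- numeric(L)
  if (kind == "zempa_ok") {
    # most instruments invalid, every bias distinct: ZEMPA still holds
    n_invalid <- ceiling(0.75 * L)
    bias[seq_len(n_invalid)] <- seq(0.6, 2.4, length.out = n_invalid) *
      rep_len(c(1, -1), n_invalid)
  } else if (kind == "zempa_violated") {
    # an identical-bias cluster larger than the valid set; the remaining
    # invalid instruments get widely separated distinct biases so the
    # shared-bias peak dominates the smoothed density
    n_valid <- 2L
    n_cluster <- max(3L, round(L / 4))
    n_spread <- L - n_valid - n_cluster
    spread <- seq(-6, 6, length.out = n_spread) + 0.033
    bias[seq_len(L - n_valid)] <- c(rep(1.2, n_cluster), spread)
  } else if (kind == "inside_violated") {
    n_invalid <- floor(L / 2)
    ord <- order(bx, decreasing = TRUE)[seq_len(n_invalid)]
    bias[ord] <- 2.5 * bx[ord]  # pleiotropy tracks instrument strength
  }
  alpha <- bias * bx
  by <- beta * bx + alpha + stats::rnorm(L, 0, sy / 2)
  bxh <- bx + stats::rnorm(L, 0, sx / 2)
  data <- mr_summary(beta_exposure = bxh, se_exposure = sx,
                     beta_outcome = by, se_outcome = sy)
  attr(data, "truth_beta") <- beta
  attr(data, "bias") <- bias
  attr(data, "valid") <- bias == 0
  if (!is.null(path)) {
    write_summary_table(data, path)
    jsonlite::write_json(
      list(kind = kind, L = L, seed = seed, truth_beta = beta,
           bias = bias, valid = bias == 0),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  data
}
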