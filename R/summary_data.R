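#' Assemble a per-variant summary-statistics dataset
#'
#' Container for two-sample Mendelian randomization summary data: for each
#' genetic variant j, the SNP-exposure association estimate \eqn{\hat\beta_{Xj}}
#' with standard error \eqn{\sigma_{Xj}} and the SNP-outcome association
#' estimate \eqn{\hat\beta_{Yj}} with standard error \eqn{\sigma_{Yj}}.
#'
#' @param snp character vector of variant identifiers (defaults to
#'   `snp1 ... snpL`).
#' @param beta_exposure,se_exposure numeric vectors: SNP-exposure association
#'   estimates and their standard errors.
#' @param beta_outcome,se_outcome numeric vectors: SNP-outcome association
#'   estimates and their standard errors.
#'
#' @return A data frame of class `mr_summary` with columns `snp`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`.
#'
#' @details All four value vectors must have equal length L >= 1, contain only
#'   finite values, and both standard-error vectors must be strictly positive.
#'
#' @examples
#' d <- mr_summary(beta_exposure = c(0.1, 0.12, 0.09),
#'                 se_exposure   = c(0.01, 0.01, 0.012),
#'                 beta_outcome  = c(0.05, 0.07, 0.04),
#'                 se_outcome    = c(0.02, 0.02, 0.025))
#' compute_ratios(d)
#' @export
mr_summary <- function(beta_exposure, se_exposure, beta_outcome, se_outcome,
                       snp = NULL) {
  L <- length(beta_exposure)
  if (L < 1L) stop("at least one variant is required")
  vals <- list(beta_exposure = beta_exposure, se_exposure = se_exposure,
               beta_outcome = beta_outcome, se_outcome = se_outcome)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v)) stop(sprintf("'%s' must be numeric", nm))
    if (length(v) != L)
      stop(sprintf("'%s' has length %d, expected %d", nm, length(v), L))
    if (any(!is.finite(v)))
      stop(sprintf("'%s' contains non-finite values", nm))
  }
  if (any(se_exposure <= 0)) stop("'se_exposure' must be strictly positive")
  if (any(se_outcome <= 0)) stop("'se_outcome' must be strictly positive")
  if (is.null(snp)) snp <- paste0("snp", seq_len(L))
  if (length(snp) != L) stop("'snp' length does not match the value vectors")
  out <- data.frame(snp = as.character(snp),
                    beta_exposure = as.numeric(beta_exposure),
                    se_exposure = as.numeric(se_exposure),
                    beta_outcome = as.numeric(beta_outcome),
                    se_outcome = as.numeric(se_outcome),
                    stringsAsFactors = FALSE)
  class(out) <- c("mr_summary", "data.frame")
  out
}

#' Number of instruments in a summary dataset
#' @param data an [mr_summary] dataset.
#' @return integer count of variants L.
#' @export
n_instruments <- function(data) nrow(data)

#' Per-variant ratio (Wald) estimates and their standard errors
#'
#' Computes the per-variant causal ratio estimate
#' \eqn{\hat\beta_{Rj} = \hat\beta_{Yj}/\hat\beta_{Xj}} together with its
#' delta-method standard error
#' \deqn{\sigma_{Rj} = \sqrt{\sigma_{Yj}^2/\hat\beta_{Xj}^2 +
#'   \hat\beta_{Yj}^2 \sigma_{Xj}^2/\hat\beta_{Xj}^4}}
#' and its simplification under the NO-Measurement-Error (NOME) assumption,
#' \eqn{\sigma_{Yj}/|\hat\beta_{Xj}|}, which treats the SNP-exposure estimate
#' as error-free.
#'
#' @param data an [mr_summary] dataset; every `beta_exposure` must be nonzero.
#' @return A data frame of class `ratio_set` with columns `snp`, `ratio`,
#'   `se_full`, `se_nome`. The NOME standard error never exceeds the full
#'   delta-method one.
#' @export
compute_ratios <- function(data) {
  stopifnot(inherits(data, "mr_summary"))
  bad <- which(data$beta_exposure == 0 | !is.finite(data$beta_exposure))
  if (length(bad))
    stop("invalid instrument (zero or non-finite SNP-exposure estimate): ",
         paste(data$snp[bad], collapse = ", "))
  bx <- data$beta_exposure
  by <- data$beta_outcome
  sx <- data$se_exposure
  sy <- data$se_outcome
  out <- data.frame(
    snp = data$snp,
    ratio = by / bx,
    se_full = sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4),
    se_nome = sy / abs(bx),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ratio_set", "data.frame")
  out
}

#' Standardized instrument weights
#'
#' Inverse-variance weights for the weighted mode-based estimate,
#' \eqn{w_j = \sigma_{Rj}^{-2} / \sum_j \sigma_{Rj}^{-2}}, or equal weights
#' \eqn{w_j = 1/L} for the simple (unweighted) version.
#'
#' @param ratios a `ratio_set` from [compute_ratios()].
#' @param weighting `"simple"` (equal weights) or `"weighted"`
#'   (inverse-variance).
#' @param nome logical; when `TRUE` the NOME standard errors are used in the
#'   inverse-variance weights, otherwise the full delta-method ones.
#' @return numeric vector of nonnegative weights summing to 1.
#' @export
standardized_weights <- function(ratios, weighting = c("weighted", "simple"),
                                 nome = FALSE) {
  weighting <- match.arg(weighting)
  L <- nrow(ratios)
  if (weighting == "simple") return(rep(1 / L, L))
  se <- if (nome) ratios$se_nome else ratios$se_full
  if (any(se <= 0)) stop("standard errors must be strictly positive")
  w <- se^-2
  w / sum(w)
}
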