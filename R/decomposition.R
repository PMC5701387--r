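# simple intercept+slope OLS residuals via stats::lm.fit
ols_residuals <- function(y, x) {
  fit <- lm.fit(cbind(`(Intercept)` = 1, x = x), y)
  list(residuals = unname(fit$residuals),
       intercept = unname(fit$coefficients[1]),
       slope = unname(fit$coefficients[2]),
       r_squared = 1 - sum(fit$residuals^2) / sum((y - mean(y))^2))
}

#' Regress reporter fluorescence on cell size
#'
#' First stage of the size-expression decomposition: ordinary least squares
#' of each channel's population mean fluorescence on the mean cell size S
#' (intercept + slope). The residuals, `mC_reg` and `mV_reg`, are the
#' size-normalized per-strain fluorescence signals. QC-failed strains are
#' excluded, not imputed.
#'
#' @param summaries strain summary table (columns `strain_id`, `S`, `mV`,
#'   `mC`, optional `qc_pass`).
#' @param scale `"raw"` (default, regression on the summary values as
#'   reported) or `"log"` (all three variables log-transformed first).
#' @return list with `strain_id`, residual vectors `mC_reg` and `mV_reg`
#'   (strain order preserved), `S` as used in the fit, and a `coefficients`
#'   data frame (intercept, slope, r_squared per channel).
#' @export
regress_out_size <- function(summaries, scale = c("raw", "log")) {
  scale <- match.arg(scale)
  ss <- as.data.frame(summaries)
  if ("qc_pass" %in% names(ss)) ss <- ss[ss$qc_pass, ]
  if (nrow(ss) < 3L) stop("need at least 3 strains")
  tf <- if (scale == "log") log else identity
  S <- tf(ss$S)
  if (sd(S) == 0) stop("degenerate fit: S is constant across strains")
  fC <- ols_residuals(tf(ss$mC), S)
  fV <- ols_residuals(tf(ss$mV), S)
  list(strain_id = ss$strain_id, S = S,
       mC_reg = fC$residuals, mV_reg = fV$residuals,
       coefficients = data.frame(
         channel = c("mC", "mV"),
         intercept = c(fC$intercept, fV$intercept),
         slope = c(fC$slope, fV$slope),
         r_squared = c(fC$r_squared, fV$r_squared)),
       scale = scale)
}

#' Global expression score E
#'
#' Second stage: the size-normalized global expression score is the pairwise
#' average of the two channels' size-regression residuals,
#' `E_i = (mC_reg_i + mV_reg_i) / 2`. The standardized variant (each
#' residual vector z-scaled before averaging) weights the channels equally
#' regardless of their dispersion; it is off by default and incompatible
#' with the antisymmetric G construction of [compute_G()].
#'
#' @param mC_reg,mV_reg residual vectors from [regress_out_size()], equal
#'   length and same strain order.
#' @param standardized z-scale each residual vector before averaging.
#' @return numeric vector E, one value per strain.
#' @export
compute_E <- function(mC_reg, mV_reg, standardized = FALSE) {
  if (length(mC_reg) != length(mV_reg))
    stop("residual vectors must have equal length")
  if (standardized) {
    zs <- function(x) (x - mean(x)) / sd(x)
    (zs(mC_reg) + zs(mV_reg)) / 2
  } else {
    (mC_reg + mV_reg) / 2
  }
}

#' Gene-specific score G
#'
#' Third stage: the gene-specific imbalance score is the residual of
#' regressing `mC_reg` on E. Because E is the unweighted mean of the two
#' residual vectors, the residual of `mV_reg` on E is exactly the negative
#' of this, so the two channels yield identical sets of absolute values;
#' this antisymmetry is asserted within `tol` and its violation signals
#' that E was not the unweighted mean of the supplied residuals. Positive
#' `G_signed` means mCherry sits above mVenus after size and
#' global-expression normalization. When E has zero variance the OLS slope
#' is undefined and the continuous limit, mean-centering
#' (`G_signed = mC_reg - mean(mC_reg)`), is used.
#'
#' @inheritParams compute_E
#' @param E global expression score from [compute_E()] (unstandardized);
#'   recomputed when omitted.
#' @param tol antisymmetry assertion tolerance (relative to the residual
#'   magnitude).
#' @return numeric vector `G_signed`, one value per strain.
#' @export
compute_G <- function(mC_reg, mV_reg, E = NULL, tol = 1e-8) {
  if (length(mC_reg) != length(mV_reg))
    stop("residual vectors must have equal length")
  E <- E %||% compute_E(mC_reg, mV_reg)
  if (var(E) == 0) {
    rC <- mC_reg - mean(mC_reg)
    rV <- mV_reg - mean(mV_reg)
  } else {
    rC <- ols_residuals(mC_reg, E)$residuals
    rV <- ols_residuals(mV_reg, E)$residuals
  }
  scale <- max(abs(rC), abs(rV), 1)
  if (max(abs(rC + rV)) > tol * scale)
    stop("internal-consistency error: residuals of mC_reg and mV_reg on E ",
         "are not antisymmetric; E must be the unweighted mean of the ",
         "supplied residuals")
  rC
}

#' Full size-expression decomposition of a screen
#'
#' Runs the three sequential stages — size regression, global expression
#' averaging, gene-specific residualization — on a strain summary table and
#' attaches the regression coefficients and the correlation report.
#'
#' @inheritParams regress_out_size
#' @return `data.frame` (class `sizexpr_decomposition`) with columns
#'   `strain_id`, `S`, `mC_reg`, `mV_reg`, `E`, `G_signed`; attributes
#'   `coefficients` and `correlations`.
#' @export
decompose_screen <- function(summaries, scale = c("raw", "log")) {
  reg <- regress_out_size(summaries, scale)
  E <- compute_E(reg$mC_reg, reg$mV_reg)
  G <- compute_G(reg$mC_reg, reg$mV_reg, E)
  out <- data.frame(strain_id = reg$strain_id, S = reg$S,
                    mC_reg = reg$mC_reg, mV_reg = reg$mV_reg,
                    E = E, G_signed = G)
  structure(out, class = c("sizexpr_decomposition", "data.frame"),
            coefficients = reg$coefficients,
            correlations = correlation_report(summaries, out))
}

#' Pearson correlations among raw and decomposed scores
#'
#' Correlation matrix among the raw channel means (`mV`, `mC`), cell size
#' `S`, global expression `E` and the magnitude of the gene-specific score
#' `|G|`, with pairwise-complete handling of strains excluded upstream.
#' Pairs involving a constant vector are reported as `NA`.
#'
#' @param summaries strain summary table.
#' @param decomposition decomposition table from [decompose_screen()] (or a
#'   data frame with `strain_id`, `E`, `G_signed`).
#' @return 5 x 5 correlation matrix over `mV`, `mC`, `S`, `E`, `absG`.
#' @export
correlation_report <- function(summaries, decomposition) {
  ss <- as.data.frame(summaries)
  if ("qc_pass" %in% names(ss)) ss <- ss[ss$qc_pass, ]
  if (nrow(ss) < 3L) stop("need at least 3 strains")
  idx <- match(ss$strain_id, decomposition$strain_id)
  m <- cbind(mV = ss$mV, mC = ss$mC, S = ss$S,
             E = decomposition$E[idx],
             absG = abs(decomposition$G_signed[idx]))
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  sds <- apply(m, 2, function(x) sd(x[is.finite(x)]))
  const <- which(!is.finite(sds) | sds == 0)
  if (length(const)) {
    r[const, ] <- NA_real_
    r[, const] <- NA_real_
    diag(r) <- ifelse(seq_len(ncol(m)) %in% const, NA_real_, 1)
  }
  r
}
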