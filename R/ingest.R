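#' Read a per-well event file
#'
#' Reads one cytometry event file (delimited text or FCS 3.x) into an event
#' table with columns `fsc`, `mvenus`, `mcherry`. The instrument channel
#' names are configurable through `channels`; metadata (`plate`, `well`,
#' `strain_id`) is taken from the `PLATE_WELL` file-name convention and,
#' when a `layout` table is supplied, from the layout join.
#'
#' @param path event file path; format is inferred from the extension
#'   (`.fcs` versus anything else) unless `format` is given.
#' @param format `"delimited"` or `"fcs"`; default inferred.
#' @param channels named character vector mapping the internal names
#'   `fsc`, `mvenus`, `mcherry` to the channel names in the file.
#' @param layout optional layout table (`plate`, `well`, `strain_id`, ...)
#'   used to attach the strain id.
#' @return `data.table` with columns `fsc`, `mvenus`, `mcherry` and, when
#'   available, `plate`, `well`, `strain_id`.
#' @export
read_events <- function(path, format = NULL,
                        channels = c(fsc = "FSC-H", mvenus = "mVenus",
                                     mcherry = "mCherry"),
                        layout = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- format %||%
    (if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "delimited")
  if (format == "fcs") {
    m <- read_fcs(path)
    tab <- as.data.table(m)
  } else {
    tab <- fread(path)
  }
  if (nrow(tab) == 0L) stop("empty event file: ", path)
  missing <- setdiff(channels, names(tab))
  if (length(missing))
    stop("missing channel(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  out <- data.table(fsc = as.numeric(tab[[channels[["fsc"]]]]),
                    mvenus = as.numeric(tab[[channels[["mvenus"]]]]),
                    mcherry = as.numeric(tab[[channels[["mcherry"]]]]))
  stem <- sub("\\.[^.]+$", "", basename(path))
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  if (length(parts) == 2L) {
    plate <- suppressWarnings(as.integer(sub("^P", "", parts[1])))
    out[, plate := plate]
    out[, well := parts[2]]
    if (!is.null(layout)) {
      hit <- layout$strain_id[layout$plate == plate & layout$well == parts[2]]
      if (length(hit) == 1L) out[, strain_id := hit]
    }
  }
  out[]
}

# trimmed vector: drop values outside the symmetric [trim, 1 - trim]
# percentile band (type-7 quantiles); trim = 0 keeps everything
trim_band <- function(x, trim) {
  if (trim <= 0) return(x)
  q <- quantile(x, c(trim, 1 - trim), names = FALSE, type = 7)
  x[x >= q[1] & x <= q[2]]
}

#' Summarize one strain's events into population statistics
#'
#' Events are gated by symmetric percentile trimming on FSC (default 1% per
#' tail); population means of all three channels are the arithmetic means of
#' the gated events (`stat = "median"` substitutes medians). Per-channel CVs
#' are computed on the gated events after an additional independent trim of
#' that channel's own tails. Strains with fewer than `min_events` gated
#' events are returned as quality failures (`qc_pass = FALSE`, statistics
#' `NA`) with the reason recorded, and are excluded downstream.
#'
#' @param events event table with columns `fsc`, `mvenus`, `mcherry` and
#'   optional metadata columns `strain_id`, `plate`, `well`.
#' @param trim trim fraction per tail in (0, 0.5); 0 disables trimming.
#' @param min_events minimum gated events required (default 200).
#' @param stat population statistic, `"mean"` (default) or `"median"`.
#' @return one-row `data.frame` with columns `strain_id`, `plate`, `well`,
#'   `n_events`, `S`, `mV`, `mC`, `cv_S`, `cv_mV`, `cv_mC`, `qc_pass`,
#'   `qc_reason`.
#' @export
summarize_strain <- function(events, trim = 0.01, min_events = 200L,
                             stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)")
  meta <- list(
    strain_id = if ("strain_id" %in% names(events)) events$strain_id[1] else NA_character_,
    plate = if ("plate" %in% names(events)) events$plate[1] else NA_integer_,
    well = if ("well" %in% names(events)) events$well[1] else NA_character_)
  core <- summarize_core(events$fsc, events$mvenus, events$mcherry,
                         trim, min_events, stat)
  cbind(as.data.frame(meta), as.data.frame(core))
}

summarize_core <- function(fsc, mvenus, mcherry, trim, min_events, stat) {
  keep <- rep(TRUE, length(fsc))
  if (trim > 0) {
    q <- quantile(fsc, c(trim, 1 - trim), names = FALSE, type = 7)
    keep <- fsc >= q[1] & fsc <= q[2]
  }
  n <- sum(keep)
  if (n < min_events) {
    return(list(n_events = n, S = NA_real_, mV = NA_real_, mC = NA_real_,
                cv_S = NA_real_, cv_mV = NA_real_, cv_mC = NA_real_,
                qc_pass = FALSE,
                qc_reason = sprintf("too few events after gating (%d < %d)",
                                    n, min_events)))
  }
  center <- if (stat == "mean") mean else median
  cv <- function(x) {
    xt <- trim_band(x, trim)
    if (length(xt) < 2L) return(NA_real_)
    sd(xt) / mean(xt)
  }
  list(n_events = n,
       S = center(fsc[keep]), mV = center(mvenus[keep]),
       mC = center(mcherry[keep]),
       cv_S = cv(fsc[keep]), cv_mV = cv(mvenus[keep]), cv_mC = cv(mcherry[keep]),
       qc_pass = TRUE, qc_reason = NA_character_)
}

#' Summarize every strain of a screen
#'
#' Applies [summarize_strain()] per strain over a combined event table.
#'
#' @param events combined event table with a `strain_id` column (e.g. the
#'   `events` element of [generate_screen()]).
#' @inheritParams summarize_strain
#' @return `data.frame` of strain summaries, one row per strain, in first
#'   appearance order.
#' @export
summarize_screen <- function(events, trim = 0.01, min_events = 200L,
                             stat = c("mean", "median")) {
  stat <- match.arg(stat)
  ev <- as.data.table(events)
  if (!"strain_id" %in% names(ev)) stop("events need a strain_id column")
  if (!"plate" %in% names(ev)) ev[, plate := NA_integer_]
  if (!"well" %in% names(ev)) ev[, well := NA_character_]
  out <- ev[, summarize_core(fsc, mvenus, mcherry, trim, min_events, stat),
            by = .(strain_id, plate, well)]
  as.data.frame(out)
}

#' Estimate replicate measurement error
#'
#' One-way random-effects decomposition of log-scale strain summaries into a
#' replicate (within-strain, across-day) variance component and an
#' across-strain variance, per variable. The replicate component is the mean
#' of the per-strain sample variances across days; the across-strain
#' variance is the variance of per-strain means, taken from the full-screen
#' summary table when one is supplied (the replicate subset otherwise). The
#' ratio replicate/across-strain quantifies how far measurement error sits
#' below the biological signal.
#'
#' @param replicate_summaries summaries keyed by (strain, day): columns
#'   `strain_id`, `day`, and the summary variables.
#' @param screen_summaries optional full-screen summary table used for the
#'   across-strain variance.
#' @param variables summary columns to decompose.
#' @param log_scale decompose on the log scale (default; multiplicative
#'   error model).
#' @return `data.frame` with one row per variable: `replicate_var`,
#'   `across_var`, `ratio`.
#' @export
estimate_replicate_error <- function(replicate_summaries,
                                     screen_summaries = NULL,
                                     variables = c("S", "mV", "mC"),
                                     log_scale = TRUE) {
  rs <- as.data.frame(replicate_summaries)
  if (!all(c("strain_id", "day") %in% names(rs)))
    stop("replicate summaries need strain_id and day columns")
  days_per_strain <- table(rs$strain_id)
  if (length(days_per_strain) < 2L)
    stop("need at least 2 strains with replicate days")
  if (any(days_per_strain < 2L))
    stop("every strain needs >= 2 replicate days (ratio undefined otherwise): ",
         paste(head(names(days_per_strain)[days_per_strain < 2L], 5),
               collapse = ", "))
  tf <- if (log_scale) log else identity
  out <- lapply(variables, function(v) {
    x <- tf(rs[[v]])
    by_strain <- split(x, rs$strain_id)
    within <- mean(vapply(by_strain, var, numeric(1)))
    strain_means <- if (is.null(screen_summaries)) {
      vapply(by_strain, mean, numeric(1))
    } else {
      ss <- as.data.frame(screen_summaries)
      if ("qc_pass" %in% names(ss)) ss <- ss[ss$qc_pass, ]
      tf(ss[[v]])
    }
    across <- var(strain_means)
    data.frame(variable = v, replicate_var = within, across_var = across,
               ratio = if (across > 0) within / across else NA_real_)
  })
  do.call(rbind, out)
}

#' Plate-shift quality control by resampling
#'
#' Compares each plate's median of each summary variable to the empirical
#' distribution of medians of random same-size strain subsets drawn without
#' replacement from the whole screen. A plate is flagged on a variable when
#' its median falls outside the two-sided empirical band at level `alpha`,
#' Bonferroni-corrected across plates — a quantitative version of the usual
#' visual plate-versus-dataset comparison.
#'
#' @param summaries strain summary table with a `plate` column; QC-failed
#'   strains (`qc_pass == FALSE`) are excluded.
#' @param B number of resamples (>= 1000).
#' @param seed RNG seed; identical seeds give identical reports.
#' @param alpha two-sided flagging level before Bonferroni correction
#'   (default 0.01).
#' @param variables summary columns to check.
#' @return `data.frame` with one row per plate and variable: plate median,
#'   null-band bounds and flag; attributes `B`, `seed`, `alpha`,
#'   `flagged_plates`.
#' @export
plate_shift_qc <- function(summaries, B = 1000L, seed = 1L, alpha = 0.01,
                           variables = c("S", "mV", "mC")) {
  ss <- as.data.frame(summaries)
  if ("qc_pass" %in% names(ss)) ss <- ss[ss$qc_pass, ]
  plates <- sort(unique(ss$plate))
  if (length(plates) < 2L) stop("need at least 2 plates")
  if (B < 1000L) stop("B must be >= 1000")
  n <- nrow(ss)
  sizes <- vapply(plates, function(p) sum(ss$plate == p), 1L)
  if (any(sizes > n)) stop("plate size exceeds total strains")
  a2 <- alpha / 2 / length(plates)   # Bonferroni across plates
  rows <- list()
  null_medians <- with_seed(seed, {
    res <- list()
    for (k in unique(sizes)) {
      med <- matrix(NA_real_, nrow = B, ncol = length(variables),
                    dimnames = list(NULL, variables))
      for (b in seq_len(B)) {
        idx <- sample.int(n, k)
        for (v in variables) med[b, v] <- median(ss[[v]][idx])
      }
      res[[as.character(k)]] <- med
    }
    res
  })
  for (j in seq_along(plates)) {
    p <- plates[j]
    med <- null_medians[[as.character(sizes[j])]]
    for (v in variables) {
      bounds <- quantile(med[, v], c(a2, 1 - a2), names = FALSE, type = 7)
      obs <- median(ss[[v]][ss$plate == p])
      rows[[length(rows) + 1L]] <- data.frame(
        plate = p, variable = v, n_strains = sizes[j], median = obs,
        lower = bounds[1], upper = bounds[2],
        flag = obs < bounds[1] | obs > bounds[2])
    }
  }
  report <- do.call(rbind, rows)
  structure(report, B = B, seed = seed, alpha = alpha,
            flagged_plates = sort(unique(report$plate[report$flag])))
}
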