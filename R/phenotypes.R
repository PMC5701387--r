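#' Across-screen Z-scores
#'
#' Standardizes a per-strain score against the whole screen:
#' `(x - mean(x)) / sd(x)` with the sample (n - 1) SD convention.
#'
#' @param values numeric vector of per-strain scores (length >= 2, nonzero
#'   SD).
#' @return numeric vector of Z-scores.
#' @export
zscores <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  s <- sd(values)
  if (!is.finite(s) || s == 0) stop("zero SD: Z-scores undefined")
  (values - mean(values)) / s
}

#' Extreme-phenotype quantile bins
#'
#' Rank-based binning into the top and bottom `q` quantile tails. Values are
#' sorted ascending with stable tie-breaking by strain id; the low bin is
#' ranks `1..ceiling(q*n)` and the high bin is ranks above
#' `floor((1-q)*n)`, so bin sizes are `ceiling(q*n)` and
#' `n - floor((1-q)*n)` for every n and q.
#'
#' @param values numeric per-strain scores.
#' @param q tail fraction in (0, 0.5); default 0.05 (top/bottom 5%).
#' @param ids strain ids used for deterministic tie-breaking; defaults to
#'   the element index.
#' @return factor with levels `low`, `none`, `high`, aligned with `values`.
#' @export
quantile_bins <- function(values, q = 0.05, ids = NULL) {
  n <- length(values)
  if (q <= 0 || q >= 0.5) stop("q must be in (0, 0.5)")
  if (n < 1 / q) stop("need at least 1/q strains (n = ", n, ")")
  ids <- ids %||% as.character(seq_len(n))
  ord <- order(values, ids)
  labels <- rep("none", n)
  labels[ord[seq_len(ceiling(q * n))]] <- "low"
  hi_from <- floor((1 - q) * n) + 1L
  labels[ord[hi_from:n]] <- "high"
  factor(labels, levels = c("low", "none", "high"))
}

#' Overlaps among extreme-phenotype sets
#'
#' Set arithmetic behind the extreme-phenotype Venn diagram: pairwise
#' intersection counts among the S-high, S-low, E-high, E-low and G-extreme
#' strain sets, the unique-strain union, and the fraction of the union
#' carrying exactly one extreme label.
#'
#' @param s_bins,e_bins factors from [quantile_bins()] for the S and E
#'   scores.
#' @param g_extreme logical vector (or factor with level `"extreme"`)
#'   marking G-extreme strains.
#' @param ids strain ids aligned with the label vectors.
#' @return list with elements `sets` (named sizes), `pairwise` (intersection
#'   count matrix), `union` (unique strain count) and `frac_single`
#'   (fraction of the union with exactly one extreme label).
#' @export
venn_overlaps <- function(s_bins, e_bins, g_extreme, ids = NULL) {
  n <- length(s_bins)
  if (length(e_bins) != n || length(g_extreme) != n)
    stop("label vectors must come from the same strain set")
  ids <- ids %||% as.character(seq_len(n))
  if (is.factor(g_extreme)) g_extreme <- g_extreme == "extreme"
  sets <- list(S_high = ids[s_bins == "high"], S_low = ids[s_bins == "low"],
               E_high = ids[e_bins == "high"], E_low = ids[e_bins == "low"],
               G_extreme = ids[g_extreme])
  k <- length(sets)
  pairwise <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k))
    pairwise[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  all_ids <- unique(unlist(sets))
  n_labels <- (s_bins != "none") + (e_bins != "none") + g_extreme
  list(sets = vapply(sets, length, 1L), pairwise = pairwise,
       union = length(all_ids),
       frac_single = if (length(all_ids))
         sum(n_labels == 1L) / length(all_ids) else NA_real_)
}

# the 16 reachable pattern classes, in matrix order (S code descending,
# E code descending, no-flag before flag)
#' All sixteen pattern-class labels
#' @return character vector of the 16 class labels in display order.
#' @export
pattern_classes <- function() {
  out <- character(0)
  for (s in c(1L, 0L, -1L)) for (e in c(1L, 0L, -1L)) {
    if (s == 0L && e == 0L) next
    for (g in c(FALSE, TRUE)) out <- c(out, class_label(s, e, g))
  }
  out
}

class_label <- function(s, e, g) {
  fmt <- function(v) c(`-1` = "-1", `0` = "0", `1` = "+1")[as.character(v)]
  paste0("S", fmt(s), "/E", fmt(e), "/G", ifelse(g, "spec", "0"))
}

#' Classify strains into the 16-pattern matrix
#'
#' Codes each of the S and E Z-scores as `+1` (Z above `z_extreme`), `-1`
#' (below `-z_extreme`), `0` (inside the closed near-zero window) or
#' intermediate (neither). A strain is classified iff both codes are
#' non-intermediate and the pair is not (0, 0); the gene-specific flag is
#' set when `|Z_G| > z_extreme`. The reachable class space is exactly
#' `{+1, 0, -1}^2` minus `(0, 0)`, crossed with the binary flag — 16
#' classes.
#'
#' @param Z_S,Z_E,Z_G aligned Z-score vectors from [zscores()].
#' @param z_extreme extremeness threshold in SD units (default 2).
#' @param near_zero closed near-zero window in SD units (default
#'   `c(-0.5, 0.5)`).
#' @return `data.frame` with columns `s_code`, `e_code` (integer or `NA`
#'   for intermediate), `g_flag`, `classified`, `class` (label string such
#'   as `"S+1/E0/Gspec"`, `NA` when unclassified).
#' @export
classify_patterns <- function(Z_S, Z_E, Z_G, z_extreme = 2,
                              near_zero = c(-0.5, 0.5)) {
  if (z_extreme <= near_zero[2] || near_zero[1] > near_zero[2])
    stop_config("thresholds overlap: need near_zero low <= high < z_extreme")
  n <- length(Z_S)
  if (length(Z_E) != n || length(Z_G) != n)
    stop("Z vectors must be aligned")
  code <- function(z) {
    out <- rep(NA_integer_, length(z))
    out[z > z_extreme] <- 1L
    out[z < -z_extreme] <- -1L
    out[z >= near_zero[1] & z <= near_zero[2]] <- 0L
    out
  }
  s <- code(Z_S); e <- code(Z_E)
  g <- abs(Z_G) > z_extreme
  classified <- !is.na(s) & !is.na(e) & !(s == 0L & e == 0L)
  cls <- rep(NA_character_, n)
  cls[classified] <- class_label(s[classified], e[classified], g[classified])
  data.frame(s_code = s, e_code = e, g_flag = g,
             classified = classified, class = cls)
}

#' Pattern-matrix summary
#'
#' Counts classified strains per pattern class over all 16 classes.
#'
#' @param calls output of [classify_patterns()].
#' @return `data.frame` with columns `class` (all 16 labels, display order)
#'   and `n`.
#' @export
pattern_matrix <- function(calls) {
  lv <- pattern_classes()
  tab <- table(factor(calls$class, levels = lv))
  data.frame(class = lv, n = as.integer(tab))
}

empirical_p <- function(null, observed, alternative) {
  B <- length(null)
  hits <- if (alternative == "greater") sum(null >= observed)
          else sum(null <= observed)
  (1 + hits) / (B + 1)
}

bootstrap_result <- function(observed, null, B, seed, alternative) {
  structure(list(
    observed = observed, B = B,
    null_mean = mean(null),
    null_quantiles = quantile(null, c(0.025, 0.5, 0.975), names = TRUE),
    p = empirical_p(null, observed, alternative),
    seed = seed, alternative = alternative, null = null),
    class = "sizexpr_bootstrap")
}

#' @export
print.sizexpr_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap overlap test (%s): observed = %d, null mean = %.2f, p = %.4g (B = %d)\n",
              x$alternative, x$observed, x$null_mean, x$p, x$B))
  invisible(x)
}

#' Bootstrap co-occurrence of two phenotype sets
#'
#' Tests whether two strain sets overlap more (or less) than expected by
#' chance: the null redraws both sets at their observed sizes uniformly
#' without replacement from the strain universe and records the
#' intersection size; the empirical p-value uses the add-one correction
#' `p = (1 + #{null >= observed}) / (B + 1)`, so p is never exactly 0 and
#' lies in `[1/(B+1), 1]`.
#'
#' @param setA,setB character vectors of strain ids, subsets of `universe`.
#' @param universe all strains eligible for either set.
#' @param B number of bootstrap draws (>= 1000; default 10000 resolves
#'   p-values down to 1e-4).
#' @param seed RNG seed; identical seeds give identical results.
#' @param alternative `"greater"` (enrichment, default) or `"less"`
#'   (depletion).
#' @return `sizexpr_bootstrap` list: `observed`, `B`, `null_mean`,
#'   `null_quantiles`, `p`, `seed`, plus the null draws in `null`.
#' @export
bootstrap_cooccurrence <- function(setA, setB, universe, B = 10000L,
                                   seed = 1L,
                                   alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  check_subset(setA, universe, "setA")
  check_subset(setB, universe, "setB")
  if (B < 1000L) stop("B must be >= 1000")
  N <- length(universe)
  nA <- length(setA); nB <- length(setB)
  observed <- length(intersect(setA, setB))
  null <- with_seed(seed, {
    out <- integer(B)
    memb <- logical(N)
    for (b in seq_len(B)) {
      a <- sample.int(N, nA)
      bb <- sample.int(N, nB)
      memb[a] <- TRUE
      out[b] <- sum(memb[bb])
      memb[a] <- FALSE
    }
    out
  })
  bootstrap_result(observed, null, B, seed, alternative)
}

#' Bootstrap membership of a functional class in a phenotype set
#'
#' Tests whether a functional gene class (e.g. the ribosome structural
#' genes) is over-represented in a phenotype set: the null redraws random
#' classes of the same size from the universe and records their overlap
#' with the fixed phenotype set.
#'
#' @param member_set character vector of class member strain ids.
#' @param phenotype_set character vector of phenotype strain ids.
#' @inheritParams bootstrap_cooccurrence
#' @return `sizexpr_bootstrap`, as for [bootstrap_cooccurrence()].
#' @export
class_membership_test <- function(member_set, phenotype_set, universe,
                                  B = 10000L, seed = 1L,
                                  alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  check_subset(member_set, universe, "member_set")
  check_subset(phenotype_set, universe, "phenotype_set")
  if (B < 1000L) stop("B must be >= 1000")
  N <- length(universe)
  m <- length(member_set)
  pheno_idx <- match(phenotype_set, universe)
  memb <- logical(N)
  memb[pheno_idx] <- TRUE
  observed <- length(intersect(member_set, phenotype_set))
  null <- with_seed(seed, {
    out <- integer(B)
    for (b in seq_len(B)) out[b] <- sum(memb[sample.int(N, m)])
    out
  })
  bootstrap_result(observed, null, B, seed, alternative)
}

check_subset <- function(set, universe, name) {
  bad <- setdiff(set, universe)
  if (length(bad))
    stop(name, " contains ids outside the universe: ",
         paste(head(bad, 5), collapse = ", "))
}

#' Phenotype calls for a decomposed screen
#'
#' Convenience wrapper combining the quantile scheme (extreme tails of S, E
#' and the two-sided G tails) and the Z-score pattern scheme into one
#' per-strain phenotype table.
#'
#' @param decomposition output of [decompose_screen()].
#' @param q quantile tail fraction for the extreme bins (default 0.05).
#' @param z_extreme,near_zero pattern thresholds, see [classify_patterns()].
#' @return `data.frame` with strain id, quantile labels (`S_bin`, `E_bin`,
#'   `G_bin`), Z-scores, pattern codes and class label.
#' @export
call_phenotypes <- function(decomposition, q = 0.05, z_extreme = 2,
                            near_zero = c(-0.5, 0.5)) {
  d <- as.data.frame(decomposition)
  ids <- d$strain_id
  s_bin <- quantile_bins(d$S, q, ids)
  e_bin <- quantile_bins(d$E, q, ids)
  g_tails <- quantile_bins(d$G_signed, q, ids)
  g_bin <- factor(ifelse(g_tails == "none", "none", "extreme"),
                  levels = c("none", "extreme"))
  zs <- zscores(d$S); ze <- zscores(d$E); zg <- zscores(d$G_signed)
  calls <- classify_patterns(zs, ze, zg, z_extreme, near_zero)
  cbind(data.frame(strain_id = ids, S_bin = s_bin, E_bin = e_bin,
                   G_bin = g_bin, Z_S = zs, Z_E = ze, Z_G = zg),
        calls)
}
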