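#' Read a gene-to-term annotation table
#'
#' Accepts either a two-column delimited file (`term_id`, `gene_id`; an
#' optional header row is detected) or a GAF 2.x association file (gene id
#' from column 2, term id from column 5; comment lines start with `!`).
#' Duplicate (term, gene) pairs are counted once. When a strain universe is
#' supplied, genes outside it are excluded and terms left with zero mapped
#' members are dropped; the join report records both counts.
#'
#' @param path annotation file path.
#' @param universe optional character vector of analysis strain/gene ids.
#' @return `data.frame` with columns `term_id`, `term_name`, `gene_id` and
#'   attribute `join_report` (list: `n_pairs`, `n_excluded_genes`,
#'   `n_dropped_terms`).
#' @export
read_annotations <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  is_gaf <- any(startsWith(lines, "!")) ||
    (length(lines) && length(strsplit(lines[1], "\t", fixed = TRUE)[[1]]) >= 15L)
  if (is_gaf) {
    data_lines <- lines[!startsWith(lines, "!")]
    fields <- strsplit(data_lines, "\t", fixed = TRUE)
    bad <- which(vapply(fields, length, 1L) < 5L)
    if (length(bad))
      stop("unparseable GAF line(s): ",
           paste(head(which(!startsWith(lines, "!"))[bad], 10), collapse = ", "))
    tab <- data.frame(
      term_id = vapply(fields, `[[`, "", 5L),
      gene_id = vapply(fields, `[[`, "", 2L))
  } else {
    fields <- strsplit(lines, "[\t,;]|\\s+")
    fields <- lapply(fields, function(f) f[nzchar(f)])
    bad <- which(vapply(fields, length, 1L) != 2L)
    if (length(bad))
      stop("unparseable line(s) (expected 2 fields): ",
           paste(head(bad, 10), collapse = ", "))
    tab <- data.frame(term_id = vapply(fields, `[[`, "", 1L),
                      gene_id = vapply(fields, `[[`, "", 2L))
    if (nrow(tab) && tolower(tab$term_id[1]) %in% c("term", "term_id") &&
        tolower(tab$gene_id[1]) %in% c("gene", "gene_id", "strain_id"))
      tab <- tab[-1L, , drop = FALSE]
  }
  tab <- unique(tab)
  n_pairs <- nrow(tab)
  n_excluded <- 0L
  n_dropped <- 0L
  if (!is.null(universe)) {
    keep <- tab$gene_id %in% universe
    n_excluded <- sum(!keep)
    before <- length(unique(tab$term_id))
    tab <- tab[keep, , drop = FALSE]
    n_dropped <- before - length(unique(tab$term_id))
    if (n_dropped > 0L)
      message(n_dropped, " term(s) dropped with 0 mapped members")
  }
  tab$term_name <- tab$term_id
  structure(tab[, c("term_id", "term_name", "gene_id")],
            row.names = seq_len(nrow(tab)),
            join_report = list(n_pairs = n_pairs,
                               n_excluded_genes = n_excluded,
                               n_dropped_terms = n_dropped))
}

# term_id -> member vector, restricted to the universe
term_members <- function(annotations, universe) {
  ann <- as.data.frame(annotations)
  ann <- ann[ann$gene_id %in% universe, , drop = FALSE]
  split(ann$gene_id, ann$term_id)
}

term_names <- function(annotations) {
  ann <- as.data.frame(annotations)
  if (!"term_name" %in% names(ann)) ann$term_name <- ann$term_id
  nm <- ann$term_name[!duplicated(ann$term_id)]
  setNames(nm, ann$term_id[!duplicated(ann$term_id)])
}

#' Over-representation of a gene set in functional terms
#'
#' One-sided over-representation p-value per term from the 2x2 table of
#' in-set/in-term membership against the universe (Fisher's exact test,
#' i.e. the hypergeometric upper tail `P(X >= overlap)`). The EASE variant
#' subtracts one from the overlap before taking the tail (floored at 0),
#' giving a conservative score that penalizes single-gene overlaps.
#' P-values are Bonferroni-corrected across all terms tested in the call.
#'
#' @param gene_set character vector of strain/gene ids, subset of
#'   `universe`, non-empty.
#' @param annotations annotation table (`term_id`, `gene_id`, optional
#'   `term_name`), e.g. from [read_annotations()].
#' @param universe character vector of all analyzed ids.
#' @param method `"fisher"` (default) or `"ease"`.
#' @param correction multiple-testing correction; `"bonferroni"` (default)
#'   or `"none"`.
#' @return `data.frame` sorted by p: `term_id`, `term_name`, `overlap`,
#'   `set_size`, `term_size`, `universe_size`, `odds_ratio`, `p`, `p_adj`.
#' @export
overrepresentation <- function(gene_set, annotations, universe,
                               method = c("fisher", "ease"),
                               correction = c("bonferroni", "none")) {
  method <- match.arg(method)
  correction <- match.arg(correction)
  if (length(gene_set) == 0L) stop("empty gene_set")
  check_subset(gene_set, universe, "gene_set")
  members <- term_members(annotations, universe)
  if (length(members) == 0L) stop("no terms with members in the universe")
  nms <- term_names(annotations)
  N <- length(universe)
  n <- length(unique(gene_set))
  rows <- lapply(names(members), function(tid) {
    term <- unique(members[[tid]])
    K <- length(term)
    k <- length(intersect(gene_set, term))
    keff <- if (method == "ease") max(k - 1L, 0L) else k
    p <- phyper(keff - 1, K, N - K, n, lower.tail = FALSE)
    a <- k; b <- n - k; c_ <- K - k; d <- N - K - n + k
    or <- (a * d) / (b * c_)
    data.frame(term_id = tid, term_name = unname(nms[tid]), overlap = k,
               set_size = n, term_size = K, universe_size = N,
               odds_ratio = or, p = p)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- if (correction == "bonferroni") pmin(1, res$p * nrow(res))
               else res$p
  res[order(res$p, res$term_id), ]
}

# 2x2 log odds ratio of term membership in `group` vs the rest of the
# universe, with the Haldane-Anscombe 0.5 correction when any cell is zero
log_odds <- function(group, term, N) {
  a <- length(intersect(group, term))
  b <- length(group) - a
  c_ <- length(term) - a
  d <- N - length(group) - c_
  cells <- c(a, b, c_, d)
  if (any(cells == 0L)) cells <- cells + 0.5
  list(k = a,
       log_or = log(cells[1] * cells[4] / (cells[2] * cells[3])),
       se = sqrt(sum(1 / cells)))
}

#' Differential enrichment between two gene groups
#'
#' For each term, compares the term's enrichment in `groupA` against
#' `groupB` (each versus the universe): the statistic is
#' `z = (logOR_A - logOR_B) / sqrt(SE_A^2 + SE_B^2)` with log odds ratios
#' and standard errors from the 2x2 tables (Haldane 0.5 correction on zero
#' cells), alongside each group's one-sided over-representation p-value.
#' A term is flagged `differential` when it passes any of: `z` above
#' `z_single`; group-A p below `p_single`; or the combined threshold
#' `-log10(p_A) >= combined_logp` and `z >= combined_z`. Terms absent from
#' both groups are skipped.
#'
#' @param groupA,groupB character vectors of ids, subsets of `universe`
#'   (need not be disjoint; overlap is reported in the attribute
#'   `groups_disjoint`).
#' @inheritParams overrepresentation
#' @param z_single single-criterion z threshold (default 2).
#' @param p_single single-criterion p threshold (default 0.1).
#' @param combined_logp,combined_z combined threshold: `-log10(p_A)` at
#'   least `combined_logp` (default 1.3, i.e. p <= 0.05) and z at least
#'   `combined_z` (default 0.5).
#' @return `data.frame` sorted by decreasing z: per term the overlap counts
#'   `k_A`, `k_B`, `term_size`, `logOR_A`, `se_A`, `logOR_B`, `se_B`, `z`,
#'   `p_A`, `p_B`, `differential`; attributes `groups_disjoint`,
#'   `n_skipped`.
#' @export
differential_enrichment <- function(groupA, groupB, annotations, universe,
                                    z_single = 2, p_single = 0.1,
                                    combined_logp = 1.3, combined_z = 0.5) {
  check_subset(groupA, universe, "groupA")
  check_subset(groupB, universe, "groupB")
  members <- term_members(annotations, universe)
  nms <- term_names(annotations)
  N <- length(universe)
  nA <- length(unique(groupA)); nB <- length(unique(groupB))
  rows <- list()
  n_skipped <- 0L
  for (tid in names(members)) {
    term <- unique(members[[tid]])
    K <- length(term)
    loA <- log_odds(groupA, term, N)
    loB <- log_odds(groupB, term, N)
    if (loA$k == 0L && loB$k == 0L) {
      n_skipped <- n_skipped + 1L
      next
    }
    z <- (loA$log_or - loB$log_or) / sqrt(loA$se^2 + loB$se^2)
    pA <- phyper(loA$k - 1, K, N - K, nA, lower.tail = FALSE)
    pB <- phyper(loB$k - 1, K, N - K, nB, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      term_id = tid, term_name = unname(nms[tid]),
      k_A = loA$k, k_B = loB$k, term_size = K,
      logOR_A = loA$log_or, se_A = loA$se,
      logOR_B = loB$log_or, se_B = loB$se,
      z = z, p_A = pA, p_B = pB,
      differential = (z > z_single) | (pA < p_single) |
                     (-log10(pA) >= combined_logp & z >= combined_z))
  }
  if (n_skipped > 0L)
    message(n_skipped, " term(s) absent from both groups skipped")
  res <- do.call(rbind, rows)
  res <- res[order(-res$z, res$term_id), ]
  structure(res,
            groups_disjoint = length(intersect(groupA, groupB)) == 0L,
            n_skipped = n_skipped)
}

#' Phenotype-landscape summary report
#'
#' Machine-readable summary of a completed run: strain counts per pattern
#' class, the top enriched term of each supplied enrichment result, and
#' aggregate counts for user-defined system groupings (unions of pattern
#' classes mirroring e.g. division/biosynthesis, energy-protein-ribosome,
#' membrane-motility regions of the landscape).
#'
#' @param phenotypes phenotype table from [call_phenotypes()].
#' @param enrichment optional named list of enrichment result tables (from
#'   [overrepresentation()] or [differential_enrichment()]); for each, the
#'   top term (smallest p, or largest z for differential results) is
#'   reported.
#' @param systems optional named list of character vectors of class labels;
#'   each entry is summarized as the number of classified strains whose
#'   class falls in the union.
#' @return `sizexpr_landscape` list with elements `class_counts`,
#'   `n_classified`, `n_unclassified`, `top_terms`, `systems`. Use
#'   [format_landscape()] for a deterministic text serialization.
#' @export
report_landscape <- function(phenotypes, enrichment = NULL, systems = NULL) {
  ph <- as.data.frame(phenotypes)
  counts <- pattern_matrix(ph)
  top_terms <- NULL
  if (!is.null(enrichment) && length(enrichment)) {
    top_terms <- lapply(enrichment, function(res) {
      if (is.null(res) || nrow(res) == 0L) return(NULL)
      top <- if ("z" %in% names(res)) res[which.max(res$z), ]
             else res[which.min(res$p), ]
      list(term_id = top$term_id, term_name = top$term_name,
           p = unname(if ("p_adj" %in% names(top)) top$p_adj else top$p_A),
           z = if ("z" %in% names(top)) top$z else NULL)
    })
  }
  sys_counts <- NULL
  if (!is.null(systems)) {
    sys_counts <- lapply(systems, function(classes)
      sum(ph$class %in% classes, na.rm = TRUE))
  }
  structure(list(class_counts = counts,
                 n_classified = sum(ph$classified),
                 n_unclassified = sum(!ph$classified),
                 top_terms = top_terms, systems = sys_counts),
            class = "sizexpr_landscape")
}

#' Serialize a landscape report
#'
#' Deterministic YAML rendering of [report_landscape()] output; identical
#' inputs give byte-identical text.
#'
#' @param report a `sizexpr_landscape` object.
#' @return character scalar of YAML text.
#' @export
format_landscape <- function(report) {
  x <- unclass(report)
  x$class_counts <- setNames(as.list(x$class_counts$n), x$class_counts$class)
  yaml::as.yaml(x)
}

#' @export
print.sizexpr_landscape <- function(x, ...) {
  cat("Phenotype landscape:", x$n_classified, "classified /",
      x$n_unclassified, "unclassified strains\n")
  nz <- x$class_counts[x$class_counts$n > 0, ]
  for (i in seq_len(nrow(nz)))
    cat(sprintf("  %-14s %d\n", nz$class[i], nz$n[i]))
  if (!is.null(x$systems))
    for (nm in names(x$systems))
      cat(sprintf("  system %-8s %d strains\n", nm, x$systems[[nm]]))
  invisible(x)
}
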