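#' Default seeded effect-class composition
#'
#' Three phenotypic systems are seeded by default, mirroring the landscape a
#' genome-wide deletion screen exposes: DB (division & biosynthesis;
#' larger cells, higher expression), MM (membrane & motility; smaller cells,
#' lower expression) and EPR (energy/protein synthesis/ribosome; smaller
#' cells, higher expression with a gene-specific reporter imbalance). Effect
#' sizes are expressed on the log scale as multiples of the strain-to-strain
#' baseline SD `sigma_strain`, so the seeded strains sit about three
#' across-screen SDs from the null bulk.
#'
#' @param sigma_strain log-scale SD of strain-to-strain baseline variation.
#' @return list of effect-class descriptors with fields `system`, `n`,
#'   `dS`, `dE`, `dG` (log-scale effects).
#' @export
default_effect_classes <- function(sigma_strain = 0.2) {
  s <- 3 * sigma_strain
  list(
    list(system = "DB",  n = 150L, dS = +s, dE = +s, dG = 0),
    list(system = "MM",  n = 150L, dS = -s, dE = -s, dG = 0),
    list(system = "EPR", n = 90L,  dS = -s, dE = +s, dG = +s)
  )
}

#' Configure a synthetic knockout screen
#'
#' Describes the generative model of a dual-reporter cytometry screen across
#' a deletion library: each strain has a log-scale size deviation (seeded
#' effect `dS` plus Gaussian baseline noise `sigma_strain`); per-cell forward
#' scatter is lognormal around the strain size; per-cell fluorescence couples
#' to the cell's own size through the exponent `gamma` (fluorescence
#' proportional to size^gamma, the growth-feedback proxy) and adds the global
#' expression effect `dE` and the antisymmetric gene-specific effect `dG`
#' (`+dG` on mVenus, `-dG` on mCherry) plus independent lognormal channel
#' noise `sigma_cell`. Replicate days add a multiplicative lognormal shift
#' with SD `sigma_replicate`, an order of magnitude below across-strain
#' variation at the defaults.
#'
#' @param n_strains number of knockout strains (default 3822).
#' @param n_wt_controls number of wild-type control cultures appended after
#'   the knockouts (default 2).
#' @param plate_size wells per plate (default 96, filled row-major in strain
#'   order).
#' @param n_events_per_strain cytometry events acquired per strain well.
#' @param baseline_size baseline forward-scatter value (arbitrary FSC units).
#' @param baseline_fluor baseline fluorescence per channel (arbitrary units).
#' @param coupling_exponent size-to-fluorescence coupling exponent `gamma`.
#' @param sigma_strain log-scale SD of strain-to-strain baseline variation.
#' @param sigma_cell log-scale SD of per-cell noise (applied to FSC and, as
#'   independent draws, to each fluorescence channel).
#' @param sigma_replicate log-scale SD of day-to-day replicate shifts.
#' @param effect_classes list of effect classes as produced by
#'   [default_effect_classes()]; use `list()` for a null screen.
#' @param clustered_layout if `TRUE`, strains of each effect class occupy
#'   contiguous strain ids (hence contiguous plates), recreating the
#'   functionally clustered plates of arrayed libraries; if `FALSE` class
#'   members are scattered at random.
#' @param seed integer RNG seed; identical config and seed give
#'   byte-identical output.
#' @return a `sizexpr_screen_config` list.
#' @export
screen_config <- function(n_strains = 3822L, n_wt_controls = 2L,
                          plate_size = 96L, n_events_per_strain = 2000L,
                          baseline_size = 100, baseline_fluor = 1000,
                          coupling_exponent = 1, sigma_strain = 0.2,
                          sigma_cell = 0.3,
                          sigma_replicate = sqrt(0.1) * 0.2,
                          effect_classes = default_effect_classes(sigma_strain),
                          clustered_layout = FALSE, seed = 1L) {
  cfg <- list(
    n_strains = as.integer(n_strains),
    n_wt_controls = as.integer(n_wt_controls),
    plate_size = as.integer(plate_size),
    n_events_per_strain = as.integer(n_events_per_strain),
    baseline_size = baseline_size, baseline_fluor = baseline_fluor,
    coupling_exponent = coupling_exponent,
    sigma_strain = sigma_strain, sigma_cell = sigma_cell,
    sigma_replicate = sigma_replicate,
    effect_classes = effect_classes,
    clustered_layout = isTRUE(clustered_layout),
    seed = as.integer(seed)
  )
  validate_screen_config(cfg)
  structure(cfg, class = "sizexpr_screen_config")
}

validate_screen_config <- function(cfg) {
  counts <- c(cfg$n_strains, cfg$n_wt_controls, cfg$plate_size,
              cfg$n_events_per_strain)
  if (any(is.na(counts)) || any(counts[-2] <= 0L) || cfg$n_wt_controls < 0L)
    stop_config("counts must be positive")
  sds <- c(cfg$sigma_strain, cfg$sigma_cell, cfg$sigma_replicate)
  if (any(sds < 0)) stop_config("all SDs must be >= 0")
  if (cfg$baseline_size <= 0 || cfg$baseline_fluor <= 0)
    stop_config("baselines must be > 0")
  n_eff <- sum(vapply(cfg$effect_classes, function(e) as.integer(e$n), 1L))
  if (length(cfg$effect_classes) && n_eff > cfg$n_strains)
    stop_config("effect-class sizes (", n_eff, ") exceed n_strains (",
                cfg$n_strains, ")")
  invisible(cfg)
}

#' @export
print.sizexpr_screen_config <- function(x, ...) {
  cat("Synthetic screen config:", x$n_strains, "strains +", x$n_wt_controls,
      "WT controls,", x$n_events_per_strain, "events/strain\n")
  cat("  gamma =", x$coupling_exponent,
      " sigma(strain, cell, replicate) =",
      paste(signif(c(x$sigma_strain, x$sigma_cell, x$sigma_replicate), 3),
            collapse = ", "), "\n")
  for (e in x$effect_classes)
    cat(sprintf("  %-4s n=%d dS=%+.3f dE=%+.3f dG=%+.3f\n",
                e$system, e$n, e$dS, e$dE, e$dG))
  invisible(x)
}

# well label for position `pos` (1-based) on a plate with 12 columns
well_label <- function(pos) {
  row <- (pos - 1L) %/% 12L + 1L
  col <- (pos - 1L) %% 12L + 1L
  sprintf("%s%02d", LETTERS[row], col)
}

# layout + effect truth shared by generate_screen / generate_replicate_set
screen_truth <- function(cfg) {
  n <- cfg$n_strains
  ids <- sprintf("ko%04d", seq_len(n))
  genes <- sprintf("gene%04d", seq_len(n))
  system <- rep("null", n)
  dS <- dE <- dG <- numeric(n)
  classes <- cfg$effect_classes
  if (length(classes)) {
    sizes <- vapply(classes, function(e) as.integer(e$n), 1L)
    if (cfg$clustered_layout) {
      member <- split(seq_len(sum(sizes)),
                      rep(seq_along(classes), sizes))
    } else {
      picked <- with_seed(substream_seed(cfg$seed, 91L),
                          sample(n, sum(sizes)))
      member <- split(picked, rep(seq_along(classes), sizes))
    }
    for (j in seq_along(classes)) {
      idx <- member[[j]]
      system[idx] <- classes[[j]]$system
      dS[idx] <- classes[[j]]$dS
      dE[idx] <- classes[[j]]$dE
      dG[idx] <- classes[[j]]$dG
    }
  }
  all_ids <- c(ids, sprintf("WT%d", seq_len(cfg$n_wt_controls)))
  all_genes <- c(genes, rep("WT", cfg$n_wt_controls))
  m <- length(all_ids)
  pos <- seq_len(m)
  layout <- data.table(
    plate = (pos - 1L) %/% cfg$plate_size + 1L,
    well = well_label((pos - 1L) %% cfg$plate_size + 1L),
    strain_id = all_ids, gene_name = all_genes,
    is_control = c(rep(FALSE, n), rep(TRUE, cfg$n_wt_controls))
  )
  truth <- data.table(
    strain_id = all_ids,
    system = c(system, rep("wt", cfg$n_wt_controls)),
    dS = c(dS, rep(0, cfg$n_wt_controls)),
    dE = c(dE, rep(0, cfg$n_wt_controls)),
    dG = c(dG, rep(0, cfg$n_wt_controls)),
    plate = layout$plate, well = layout$well
  )
  list(layout = layout, truth = truth)
}

# strain-level log-size deviation: seeded effect + baseline noise, drawn in a
# per-strain substream so it is shared between screen and replicate draws
strain_deviation <- function(cfg, idx, dS) {
  eps <- vapply(idx, function(i)
    with_seed(substream_seed(cfg$seed, 1L, i), rnorm(1, 0, cfg$sigma_strain)),
    numeric(1))
  dS + eps
}

# per-cell event draws for one strain given its log-scale deviations
draw_events <- function(cfg, n, d, dE, dG) {
  g <- cfg$coupling_exponent
  e_s <- rnorm(n, 0, cfg$sigma_cell)
  e_v <- rnorm(n, 0, cfg$sigma_cell)
  e_c <- rnorm(n, 0, cfg$sigma_cell)
  list(
    fsc = cfg$baseline_size * exp(d + e_s),
    mvenus = cfg$baseline_fluor * exp(g * (d + e_s) + dE + dG + e_v),
    mcherry = cfg$baseline_fluor * exp(g * (d + e_s) + dE - dG + e_c)
  )
}

#' Generate a synthetic screen
#'
#' Draws per-cell events for every strain and wild-type control of a
#' configured screen, together with the plate layout, the effect ground
#' truth, and a functional annotation table in which each seeded system has
#' one concordant term (`SYS:<label>`) plus a background of random terms.
#'
#' @param config a [screen_config()] object.
#' @return a `sizexpr_screen` list with elements `events` (one
#'   `data.table` of all events with `plate`, `well`, `strain_id`, `fsc`,
#'   `mvenus`, `mcherry`), `layout`, `truth`, `annotations` (long table of
#'   `term_id`, `term_name`, `gene_id`) and `config`.
#' @export
generate_screen <- function(config) {
  cfg <- validate_screen_config(config)
  st <- screen_truth(cfg)
  truth <- st$truth
  m <- nrow(truth)
  d <- strain_deviation(cfg, seq_len(m), truth$dS)
  n_ev <- cfg$n_events_per_strain
  per_strain <- vector("list", m)
  for (i in seq_len(m)) {
    ev <- with_seed(substream_seed(cfg$seed, 2L, i),
                    draw_events(cfg, n_ev, d[i], truth$dE[i], truth$dG[i]))
    per_strain[[i]] <- data.table(
      plate = truth$plate[i], well = truth$well[i],
      strain_id = truth$strain_id[i],
      fsc = ev$fsc, mvenus = ev$mvenus, mcherry = ev$mcherry)
  }
  ann <- with_seed(substream_seed(cfg$seed, 92L),
                   annotation_truth(truth))
  structure(list(events = rbindlist(per_strain), layout = st$layout,
                 truth = truth, annotations = ann, config = cfg),
            class = "sizexpr_screen")
}

# one concordant term per seeded system plus random background terms
annotation_truth <- function(truth, n_random_terms = 20L,
                             random_term_size = 30L) {
  ko <- truth[truth$system != "wt", ]
  out <- list()
  for (sys in setdiff(unique(ko$system), "null")) {
    members <- ko$strain_id[ko$system == sys]
    out[[length(out) + 1L]] <- data.table(
      term_id = paste0("SYS:", sys),
      term_name = paste0("seeded ", sys, " system"),
      gene_id = members)
  }
  size <- min(random_term_size, nrow(ko))
  for (j in seq_len(n_random_terms)) {
    out[[length(out) + 1L]] <- data.table(
      term_id = sprintf("RND:%03d", j),
      term_name = sprintf("random background term %03d", j),
      gene_id = sample(ko$strain_id, size))
  }
  rbindlist(out)
}

#' Generate replicate-day measurements for a strain subset
#'
#' Re-measures a subset of strains on `n_days` independent days. Each
#' (strain, day, variable) gets a multiplicative lognormal shift with SD
#' `sigma_replicate` on top of the strain's true baseline (shared with
#' [generate_screen()] under the same config), and fresh per-cell sampling.
#'
#' @param config a [screen_config()] object.
#' @param strain_subset character vector of strain ids to re-measure.
#' @param n_days number of replicate days (>= 2).
#' @return `data.table` of events keyed by (strain, day) with columns
#'   `plate`, `well`, `strain_id`, `day`, `fsc`, `mvenus`, `mcherry`.
#' @export
generate_replicate_set <- function(config, strain_subset, n_days) {
  cfg <- validate_screen_config(config)
  if (length(strain_subset) == 0L) stop("empty strain subset")
  if (n_days < 2L) stop("n_days must be >= 2")
  st <- screen_truth(cfg)
  truth <- st$truth
  idx <- match(strain_subset, truth$strain_id)
  if (anyNA(idx))
    stop("unknown strain ids: ",
         paste(head(strain_subset[is.na(idx)], 5), collapse = ", "))
  d <- strain_deviation(cfg, idx, truth$dS[idx])
  n_ev <- cfg$n_events_per_strain
  out <- vector("list", length(idx) * n_days)
  k <- 0L
  for (j in seq_along(idx)) {
    i <- idx[j]
    for (day in seq_len(n_days)) {
      shift <- with_seed(substream_seed(cfg$seed, 3L, i, day),
                         rnorm(3, 0, cfg$sigma_replicate))
      ev <- with_seed(substream_seed(cfg$seed, 4L, i, day),
                      draw_events(cfg, n_ev, d[j], truth$dE[i], truth$dG[i]))
      k <- k + 1L
      out[[k]] <- data.table(
        plate = truth$plate[i], well = truth$well[i],
        strain_id = truth$strain_id[i], day = day,
        fsc = ev$fsc * exp(shift[1]),
        mvenus = ev$mvenus * exp(shift[2]),
        mcherry = ev$mcherry * exp(shift[3]))
    }
  }
  rbindlist(out)
}

#' Write a screen to disk
#'
#' Writes one event file per well (named `PLATE_WELL`, e.g. `P03_B07`) plus
#' the layout, effect-truth and annotation tables and the configuration.
#' Delimited event files are tab-separated with header columns `FSC-H`,
#' `mVenus`, `mCherry`, printed at 10 significant digits so identical screens
#' produce byte-identical files; FCS files are written with [write_fcs()].
#'
#' @param screen a `sizexpr_screen` from [generate_screen()].
#' @param dir output directory (created if needed).
#' @param format `"delimited"` or `"fcs"`.
#' @return character vector of event file paths, invisibly.
#' @export
write_screen <- function(screen, dir, format = c("delimited", "fcs")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "fcs") ".fcs" else ".tsv"
  ev <- screen$events
  files <- character(0)
  for (sub in split(ev, by = c("plate", "well"), sorted = TRUE)) {
    stem <- sprintf("P%02d_%s", sub$plate[1], sub$well[1])
    path <- file.path(dir, paste0(stem, ext))
    m <- cbind(`FSC-H` = sub$fsc, mVenus = sub$mvenus, mCherry = sub$mcherry)
    if (format == "fcs") {
      write_fcs(m, path)
    } else {
      txt <- apply(m, 1, function(r) paste(sprintf("%.10g", r), collapse = "\t"))
      writeLines(c("FSC-H\tmVenus\tmCherry", txt), path)
    }
    files <- c(files, path)
  }
  fwrite(screen$layout, file.path(dir, "layout.tsv"), sep = "\t")
  fwrite(screen$truth, file.path(dir, "truth.tsv"), sep = "\t")
  fwrite(screen$annotations, file.path(dir, "annotations.tsv"), sep = "\t")
  write_screen_config(screen$config, file.path(dir, "config.yaml"))
  invisible(files)
}

#' Write / read a screen configuration
#'
#' Configurations round-trip through a nestable key/value YAML document.
#'
#' @param config a [screen_config()] object.
#' @param path file path.
#' @return `read_screen_config` returns a `sizexpr_screen_config`.
#' @export
write_screen_config <- function(config, path) {
  writeLines(yaml::as.yaml(unclass(config), precision = 15L), path)
  invisible(path)
}

#' @rdname write_screen_config
#' @export
read_screen_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(screen_config, raw)
}
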