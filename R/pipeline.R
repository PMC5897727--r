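#' Run configuration for the end-to-end pipeline
#'
#' Defaults follow the acquisition and analysis settings the pipeline
#' targets: a 5 um surface band, global Otsu binarisation, length-weighted
#' border means, enrichment threshold `k`, 15 degree angular bins, the
#' variance-homogeneity-gated t-test, and two-tailed tests throughout.
#'
#' @param band_depth_um surface band depth (um).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold fixed threshold (when `threshold_method = "fixed"`).
#' @param enrichment_k profile enrichment threshold multiplier.
#' @param min_cells minimum cells for a valid embryo score.
#' @param bin_width_deg angular histogram bin width.
#' @param variance_rule two-sample t-test variance rule.
#' @param seed integer seed for any stochastic step.
#' @param out_dir output directory (NULL = write nothing).
#' @return list of class `run_config`.
#' @export
run_config <- function(band_depth_um = 5, threshold_method = "otsu",
                       threshold = NULL, enrichment_k = 1.5,
                       min_cells = 35L, bin_width_deg = 15,
                       variance_rule = "auto", seed = 1L, out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

#' Build a blinded manifest of phantom embryos for a two-group cohort
#'
#' Assigns each embryo a sequential code that does not reflect its genotype;
#' per-embryo processing sees only the code, and genotypes are joined back
#' only at the final statistical stage (mirroring analysis blinded to
#' genotype).
#'
#' @param n_per_group embryos per genotype.
#' @param control_params,mutant_params [sheet_phantom_params()] templates;
#'   each embryo gets a fresh seed derived from `seed`.
#' @param seed integer seed controlling the per-embryo seeds and code
#'   shuffling.
#' @return data.frame manifest: `code`, `embryo_id`, `genotype`, `seed`.
#' @export
phantom_cohort_manifest <- function(n_per_group, control_params,
                                    mutant_params, seed = 1L) {
  n <- 2L * n_per_group
  run_seeded(seed, {
    seeds <- sample.int(.Machine$integer.max %/% 2L, n)
    genotype <- rep(c("control", "mutant"), each = n_per_group)
    ord <- sample.int(n)          # blinded sequential codes
    data.frame(code = sprintf("E%02d", seq_len(n)),
               embryo_id = paste0(genotype, "_", c(seq_len(n_per_group),
                                                   seq_len(n_per_group)))[ord],
               genotype = genotype[ord],
               seed = seeds[ord])
  })
}

# blinded per-embryo analysis: takes a code and a phantom parameter set,
# never a genotype. Returns per-cell and per-border tables plus the embryo
# enrichment score and profile orientations.
analyse_phantom_embryo <- function(code, params, config,
                                   use_3d = TRUE) {
  if (use_3d) {
    ph <- generate_sheet_stack(params)
    peeled <- extract_surface(ph$stack, band_depth_um = config$band_depth_um,
                              method = config$threshold_method,
                              threshold = config$threshold)
    proj <- surface_project(peeled$peeled)
    img <- proj$image
  } else {
    ph <- phantom_surface_image(params)
    img <- ph$image
  }
  labels <- ph$truth$cell_labels
  spacing <- params$voxel_spacing[1:2]
  graph <- build_border_graph(labels, spacing)
  measures <- measure_borders(graph, img)
  ratios <- suppressMessages(cell_enrichment_ratios(graph, measures))
  score <- embryo_enrichment_score(ratios, min_cells = config$min_cells)
  cells <- measure_cells(labels, spacing)
  profiles <- detect_profiles(graph, measures, k = config$enrichment_k)
  list(code = code, cells = cells, borders = measures, ratios = ratios,
       score = score, profiles = profiles)
}

#' Run the end-to-end pipeline over a cohort manifest
#'
#' For every embryo in the manifest: generate (or load) the stack, peel the
#' surface band, project, measure cells and borders, score the mediolateral
#' enrichment and detect supracellular profiles - all blinded to genotype.
#' Genotypes are joined only afterwards, for the group statistics: a
#' two-sample t-test on embryo enrichment scores, per-group one-sample
#' t-tests against 1, and chi-square comparisons of profile- and
#' cell-orientation distributions. Per-embryo failures are logged and
#' skipped; the run fails only if no embryo succeeds.
#'
#' @param manifest data.frame from [phantom_cohort_manifest()] with columns
#'   `code`, `embryo_id`, `genotype`, `seed`, or with a `path` column of
#'   stack files.
#' @param config a [run_config()].
#' @param params_for function(genotype) returning the
#'   [sheet_phantom_params()] template for that genotype (phantom cohorts).
#' @param use_3d run the full 3D peel/projection path (default) or the 2D
#'   surface-image path.
#' @return list of class `pipeline_result`: `per_embryo` (list),
#'   `embryo_table`, `profile_table`, `cell_table`, `stats` (list),
#'   `summaries` (audit data.frame), `skipped`.
#' @export
run_pipeline <- function(manifest, config = run_config(),
                         params_for = NULL, use_3d = TRUE) {
  if (nrow(manifest) == 0L) stop("no embryos in manifest")
  per <- list(); skipped <- list()
  for (r in seq_len(nrow(manifest))) {
    code <- manifest$code[r]
    res <- tryCatch({
      params <- params_for(manifest$genotype[r])
      params$seed <- manifest$seed[r]
      analyse_phantom_embryo(code, params, config, use_3d = use_3d)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message("embryo ", code, " skipped: ", conditionMessage(res))
      skipped[[code]] <- conditionMessage(res)
    } else per[[code]] <- res
  }
  if (length(per) == 0L) stop("no embryos succeeded")

  codes <- names(per)
  geno <- manifest$genotype[match(codes, manifest$code)]  # unblinding join
  embryo_table <- data.frame(
    code = codes, genotype = geno,
    enrichment_score = vapply(per, function(x) x$score$embryo_score,
                              numeric(1)),
    n_cells = vapply(per, function(x) x$score$n_cells, integer(1)),
    valid = vapply(per, function(x) x$score$valid, logical(1)))
  profile_table <- do.call(rbind, lapply(codes, function(cd) {
    pr <- per[[cd]]$profiles
    if (nrow(pr) == 0L) return(NULL)
    cbind(code = cd, genotype = geno[match(cd, codes)], pr)
  }))
  cell_table <- do.call(rbind, lapply(codes, function(cd)
    cbind(code = cd, genotype = geno[match(cd, codes)], per[[cd]]$cells)))

  stats_out <- list(); summaries <- list()
  groups <- split(embryo_table$enrichment_score, embryo_table$genotype)
  if (length(groups) == 2L && all(lengths(groups) >= 2L)) {
    tt <- two_sample_t(groups[[1]], groups[[2]],
                       variance_rule = config$variance_rule)
    stats_out$enrichment_between <- tt
    summaries$enrichment_between <- stat_summary_row(
      "enrichment_two_sample_t", tt, n = lengths(groups),
      options = tt$variance_rule_used)
  }
  for (gn in names(groups)) {
    if (length(groups[[gn]]) >= 2L) {
      ot <- one_sample_t(groups[[gn]], mu0 = 1)
      stats_out[[paste0("enrichment_vs_1_", gn)]] <- ot
      summaries[[paste0("enrichment_vs_1_", gn)]] <- stat_summary_row(
        paste0("one_sample_t_vs_1_", gn), ot, n = ot$n)
    }
  }
  if (!is.null(profile_table) && length(unique(profile_table$genotype)) == 2L) {
    pg <- split(profile_table$orientation_deg, profile_table$genotype)
    da <- angular_distribution(pg[[1]], config$bin_width_deg)
    db <- angular_distribution(pg[[2]], config$bin_width_deg)
    ct <- chi_square_between_groups(da, db)
    stats_out$profile_orientation_between <- ct
    summaries$profiles <- stat_summary_row("profile_orientation_chi_square",
                                           ct, n = lengths(pg))
  }
  cg <- split(cell_table$orientation_deg, cell_table$genotype)
  if (length(cg) == 2L) {
    ct <- chi_square_between_groups(
      angular_distribution(cg[[1]], config$bin_width_deg),
      angular_distribution(cg[[2]], config$bin_width_deg))
    stats_out$cell_orientation_between <- ct
    summaries$cells <- stat_summary_row("cell_orientation_chi_square", ct,
                                        n = lengths(cg))
  }

  summaries <- do.call(rbind, summaries)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(embryo_table, file.path(config$out_dir, "embryo_scores.csv"),
                config)
    if (!is.null(profile_table))
      write_table(profile_table, file.path(config$out_dir, "profiles.csv"),
                  config)
    write_table(cell_table, file.path(config$out_dir, "cells.csv"), config)
    write_table(summaries, file.path(config$out_dir, "stats_summary.csv"),
                config)
  }
  structure(list(per_embryo = per, embryo_table = embryo_table,
                 profile_table = profile_table, cell_table = cell_table,
                 stats = stats_out, summaries = summaries,
                 skipped = skipped),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", nrow(x$embryo_table), " embryos (",
      length(x$skipped), " skipped)\n", sep = "")
  print(stats::aggregate(enrichment_score ~ genotype, x$embryo_table, mean))
  invisible(x)
}
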