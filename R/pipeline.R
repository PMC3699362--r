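#' Configuration for a full pipeline run
#'
#' Exactly one of `sim_spec` (a [simulation_spec()]) or `inputs` (a list of
#' paths: `tree`, `tps_fore`, `tps_hind`, `traits`, `outline_dir`) must be
#' given.
#'
#' @param sim_spec A [simulation_spec()], or `NULL`.
#' @param inputs Named list of input paths, or `NULL`.
#' @param slide Slide semilandmarks during GPA (default `TRUE`).
#' @param branch_transform Branch-length transform for the contrast
#'   analyses (default `"exp"`, the transform reported in the study
#'   design this package follows).
#' @param n_strips Strips for RSM measurement (default 500).
#' @param n_sim Brownian simulations for the phylogenetic ANOVA
#'   (default 1000).
#' @param seed Integer seed governing every stochastic step.
#' @param out_dir Output directory for result files, or `NULL` to skip
#'   writing.
#' @return A `run_config` object.
#' @export
run_config <- function(sim_spec = NULL, inputs = NULL, slide = TRUE,
                       branch_transform = "exp", n_strips = 500,
                       n_sim = 1000, seed = 1L, out_dir = NULL) {
  if (is.null(sim_spec) == is.null(inputs)) {
    stop("exactly one of sim_spec or inputs must be given")
  }
  structure(list(sim_spec = sim_spec, inputs = inputs, slide = slide,
                 branch_transform = branch_transform,
                 n_strips = n_strips, n_sim = n_sim,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

load_wing_dataset <- function(inputs) {
  tree <- read_newick(inputs$tree)
  traits <- read_trait_table(inputs$traits)
  landmarks <- list()
  for (wg in c("fore", "hind")) {
    recs <- read_tps(inputs[[paste0("tps_", wg)]])
    for (rec in recs) {
      id <- rec$id
      parts <- strsplit(id, "[|]")[[1]]
      landmarks[[id]] <- landmark_set(
        rec$coords,
        semilandmarks = wing_landmark_template()$semilandmarks,
        specimen_id = id, taxon_id = parts[1], wing = parts[2])
    }
  }
  outlines <- list()
  files <- list.files(inputs$outline_dir, pattern = "\\.csv$",
                      full.names = TRUE)
  for (f in files) {
    id <- sub("\\.csv$", "", basename(f))
    id <- sub("^(.*)_(fore|hind)_(\\d+)$", "\\1|\\2|\\3", id)
    outlines[[id]] <- read_outline_csv(f)
  }
  ids <- names(outlines)
  parts <- strsplit(ids, "[|]")
  specimens <- data.frame(
    specimen = ids,
    taxon = vapply(parts, `[`, "", 1),
    wing = vapply(parts, `[`, "", 2),
    specimen_no = as.integer(vapply(parts, `[`, "", 3)),
    stringsAsFactors = FALSE)
  mism <- setdiff(unique(specimens$taxon), tree$tip.label)
  if (length(mism)) {
    stop("taxa present in specimen data but absent from the tree: ",
         paste(mism, collapse = ", "))
  }
  list(tree = tree, traits = traits, specimens = specimens,
       outlines = outlines, landmarks = landmarks)
}

#' Run the full wing-shape allometry pipeline
#'
#' Orchestrates every analysis stage on a simulated or loaded dataset,
#' for fore- and hindwings as separate lanes sharing one tree:
#' per-specimen RSM measurement (strip integration), GPA with sliding
#' semilandmarks over all specimens of both wings, species means,
#' linear and quadratic RSM-on-size regressions, allometric shape scores
#' and a MANCOVA of the shape variables on wing and RSM, independent
#' contrasts with branch-length transformation and through-origin
#' regression, the coloration-group general linear model, non-allometric
#' residuals, and a Brownian-simulation phylogenetic ANOVA of the
#' residual RSM on coloration group.
#'
#' @param config A [run_config()].
#' @return A `calomorph_pipeline` list with all stage results (see the
#'   methods vignette for the inventory); written to `config$out_dir` as
#'   CSV tables plus a text report when requested.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dataset <- if (!is.null(config$sim_spec)) {
    simulate_wing_dataset(config$sim_spec)
  } else {
    load_wing_dataset(config$inputs)
  }
  tree <- dataset$tree
  mism <- setdiff(unique(dataset$specimens$taxon), tree$tip.label)
  if (length(mism)) {
    stop("taxon mismatch between tree and specimens: ",
         paste(mism, collapse = ", "))
  }

  # --- stage 1: per-specimen wing geometry ---------------------------
  sp <- dataset$specimens
  geom <- t(vapply(sp$specimen, function(id) {
    ol <- dataset$outlines[[id]]
    pr <- chord_profile(ol, config$n_strips)
    c(R = pr$wing_length_R, S = pr$area_S,
      r1 = moment_radius(pr, 1), r2 = moment_radius(pr, 2),
      r3 = moment_radius(pr, 3))
  }, numeric(5)))
  rsm_table <- cbind(sp, as.data.frame(geom))

  # --- stage 2: geometric morphometrics ------------------------------
  space <- gpa(dataset$landmarks[sp$specimen], slide = config$slide)
  log_cs <- log(space$centroid_sizes)
  rsm_table$log_centroid_size <- log_cs

  # --- stage 3: species means ----------------------------------------
  spec_tab <- data.frame(taxon = sp$taxon, wing = sp$wing,
                         rsm = rsm_table$r2,
                         log_centroid_size = log_cs,
                         stringsAsFactors = FALSE)
  means <- species_means(spec_tab)
  tt <- dataset$traits
  key <- paste(means$taxon, means$wing)
  means$coloration_group <-
    tt$coloration_group[match(key, paste(tt$taxon, tt$wing))]

  # species x wing mean aligned shapes (mean of aligned coordinates,
  # shape variables recomputed from the means)
  cell <- paste(sp$taxon, sp$wing)
  cells <- sort(unique(cell))
  mean_aligned <- lapply(cells, function(cl) {
    idx <- which(cell == cl)
    Reduce(`+`, space$aligned[idx]) / length(idx)
  })
  mean_space <- space
  mean_space$aligned <- mean_aligned
  mean_space$centroid_sizes <- rep(1, length(cells))
  mean_space$labels <- data.frame(
    specimen_id = cells,
    taxon_id = sub(" (fore|hind)$", "", cells),
    wing = sub("^.* ", "", cells), stringsAsFactors = FALSE)
  sv <- shape_variables(mean_space)
  mkey <- paste(means$taxon, means$wing)
  ord <- match(cells, mkey)
  mean_rsm <- means$rsm_mean[ord]
  mean_wing <- means$wing[ord]

  # --- stage 4: raw-scale allometry ----------------------------------
  fits <- list()
  for (wg in c("fore", "hind")) {
    mw <- means[means$wing == wg, ]
    fits[[wg]] <- list(
      linear = polynomial_regression(mw$rsm_mean,
                                     mw$log_centroid_size_mean, 1),
      quadratic = polynomial_regression(mw$rsm_mean,
                                        mw$log_centroid_size_mean, 2))
  }

  # --- stage 5: shape scores + MANCOVA -------------------------------
  scores <- shape_scores(mean_space, mean_rsm)
  score_fit <- polynomial_regression(scores, mean_rsm, 1)
  # the MANCOVA needs p < error df; with few taxa, keep only the
  # highest-variance shape variables (all 2k-4 fit at the full design)
  df_e <- length(cells) - 3L
  Ymc <- sv$scores
  if (ncol(Ymc) >= df_e) {
    keep <- order(apply(Ymc, 2, stats::var),
                  decreasing = TRUE)[seq_len(df_e - 1L)]
    Ymc <- Ymc[, sort(keep), drop = FALSE]
  }
  mancova <- mancova_wilks(Ymc, factor(mean_wing), mean_rsm)

  # --- stage 6: phylogenetic analyses --------------------------------
  ttree <- transform_branch_lengths(tree, config$branch_transform)
  contrasts <- list(); contrast_fits <- list()
  glms <- list(); resids <- list(); phyl_anova <- list()
  for (wg in c("fore", "hind")) {
    mw <- means[means$wing == wg, ]
    x <- stats::setNames(mw$log_centroid_size_mean, mw$taxon)
    y <- stats::setNames(mw$rsm_mean, mw$taxon)
    cs_set <- contrast_set(ttree, x, y)
    contrasts[[wg]] <- cs_set
    contrast_fits[[wg]] <- contrast_regression(cs_set)
    glms[[wg]] <- glm_coloration(mw$rsm_mean, mw$coloration_group,
                                 mw$log_centroid_size_mean)
    res <- nonallometric_residuals(
      stats::setNames(mw$rsm_mean, mw$taxon),
      mw$log_centroid_size_mean)
    resids[[wg]] <- res
    phyl_anova[[wg]] <- phylogenetic_anova(
      tree, res[tree$tip.label],
      stats::setNames(mw$coloration_group, mw$taxon)[tree$tip.label],
      n_sim = config$n_sim, seed = config$seed + 17L)
  }

  results <- structure(list(
    config = config, tree = tree, transformed_tree = ttree,
    rsm_table = rsm_table, shape_space = space,
    species_means = means, mean_shape_variables = sv$scores,
    allometry = fits, shape_scores = scores,
    shape_score_fit = score_fit, mancova = mancova,
    contrasts = contrasts, contrast_fits = contrast_fits,
    coloration_glm = glms, nonallometric = resids,
    phylogenetic_anova = phyl_anova),
    class = "calomorph_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_results(results)
  results
}

num <- function(x, d = 6) formatC(x, digits = d, format = "g")

#' Plain-text report of a pipeline run
#'
#' One block per analysis with the statistic, degrees of freedom and
#' p-value, mirroring the result tables written to disk (the CSVs are the
#' single source of truth; the report prints the same numbers).
#'
#' @param results A `calomorph_pipeline` from [run_pipeline()].
#' @return Character vector of report lines.
#' @export
pipeline_report <- function(results) {
  if (!inherits(results, "calomorph_pipeline") ||
      is.null(results$allometry)) {
    stop("empty or invalid pipeline results")
  }
  ln <- c("Wing-shape allometry pipeline report",
          "=====================================", "")
  for (wg in c("fore", "hind")) {
    f1 <- results$allometry[[wg]]$linear
    f2 <- results$allometry[[wg]]$quadratic
    cf <- results$contrast_fits[[wg]]
    pa <- results$phylogenetic_anova[[wg]]
    gl <- results$coloration_glm[[wg]]
    ln <- c(ln, sprintf("== %swings ==", wg),
      sprintf("RSM ~ size, linear:    R^2 = %s, F_%d,%d = %s, P = %s",
              num(f1$r_squared, 3), f1$df[1], f1$df[2], num(f1$F, 4),
              num(f1$p_value, 3)),
      sprintf("RSM ~ size, quadratic: R^2 = %s, F_%d,%d = %s, P = %s",
              num(f2$r_squared, 3), f2$df[1], f2$df[2], num(f2$F, 4),
              num(f2$p_value, 3)),
      sprintf("contrast regression:   slope = %s, R^2 = %s, F_%d,%d = %s, P = %s",
              num(cf$slope, 4), num(cf$r_squared, 3), cf$df[1], cf$df[2],
              num(cf$F, 4), num(cf$p_value, 3)),
      sprintf("phylogenetic ANOVA:    F_%d,%d = %s, phylogenetic-P = %s",
              pa$df[1], pa$df[2], num(pa$F_obs, 4),
              num(pa$p_phylogenetic, 3)),
      "coloration-group GLM (partial SS):")
    tb <- gl$table
    for (r in rownames(tb)) {
      ln <- c(ln, sprintf("  %-18s df %d  SS %s  F %s  P %s", r,
                          as.integer(tb[r, "df"]), num(tb[r, "SS"], 4),
                          ifelse(is.na(tb[r, "F"]), "-", num(tb[r, "F"], 4)),
                          ifelse(is.na(tb[r, "p_value"]), "-",
                                 num(tb[r, "p_value"], 3))))
    }
    ln <- c(ln, "")
  }
  mc <- results$mancova$table
  ln <- c(ln, "== both wings: shape components ==",
    sprintf("shape score ~ RSM:  R^2 = %s, F_%d,%d = %s, P = %s",
            num(results$shape_score_fit$r_squared, 3),
            results$shape_score_fit$df[1], results$shape_score_fit$df[2],
            num(results$shape_score_fit$F, 4),
            num(results$shape_score_fit$p_value, 3)))
  for (r in rownames(mc)) {
    ln <- c(ln, sprintf(
      "MANCOVA %-10s Wilks' lambda = %s, F_%d,%d = %s, P = %s", r,
      num(mc[r, "wilks_lambda"], 4), as.integer(mc[r, "df1"]),
      as.integer(round(mc[r, "df2"])), num(mc[r, "F"], 4),
      num(mc[r, "p_value"], 3)))
  }
  ln
}

write_pipeline_results <- function(results) {
  dir <- results$config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  wr(results$rsm_table, "rsm_specimens.csv")
  wr(results$species_means, "species_means.csv")
  sv <- as.data.frame(results$mean_shape_variables)
  wr(sv, "shape_variables.csv")
  for (wg in c("fore", "hind")) {
    wr(as.data.frame(results$contrasts[[wg]]),
       paste0("contrasts_", wg, ".csv"))
  }
  write_newick(results$transformed_tree,
               file.path(dir, "tree_transformed.nwk"))
  write_tps(list(list(coords = results$shape_space$consensus,
                      id = "consensus")),
            file.path(dir, "consensus.tps"))
  writeLines(pipeline_report(results), file.path(dir, "report.txt"))
  invisible(dir)
}

#' @export
print.calomorph_pipeline <- function(x, ...) {
  cat(pipeline_report(x), sep = "\n")
  invisible(x)
}

#' Input paths for a dataset directory written by [write_wing_dataset()]
#'
#' @param dir Directory containing `tree.nwk`, `landmarks_fore.tps`,
#'   `landmarks_hind.tps`, `traits.csv` and `outlines/`.
#' @return Named list of paths suitable for [run_config()]'s `inputs`.
#' @export
wing_dataset_paths <- function(dir) {
  list(tree = file.path(dir, "tree.nwk"),
       tps_fore = file.path(dir, "landmarks_fore.tps"),
       tps_hind = file.path(dir, "landmarks_hind.tps"),
       traits = file.path(dir, "traits.csv"),
       outline_dir = file.path(dir, "outlines"))
}
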