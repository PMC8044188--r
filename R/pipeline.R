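#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one flat list.
#' Input is either a genotype file (`vcf` or `hapmap`) or a simulator
#' configuration (`sim`), plus an output directory for the stage artifacts.
#'
#' @param input Path to a VCF or HapMap file, or a [sim_config()] to
#'   simulate the panel in place.
#' @param format `"vcf"`, `"hapmap"` or `"sim"` (guessed from `input`).
#' @param out_dir Directory for stage TSV artifacts and the run log.
#' @param qc A [qc_thresholds()].
#' @param assignment A [assignment_thresholds()].
#' @param locus_class A [locus_class_thresholds()].
#' @param window_bp,segment_bp,ld_max_dist_bp,ld_threshold_r2 Diversity/LD
#'   settings.
#' @param block_max_span_bp,tag_r2_min Block and tagSNP settings.
#' @param K_values Candidate K for cross-validation.
#' @param n_restarts Restarts for the final fit.
#' @param cv_folds Cross-validation folds.
#' @param min_group_lines Minimum lines for group-frequency tables.
#' @param supergroups Optional named map base group -> supergroup.
#' @param seed Master seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, format = NULL, out_dir = tempfile("run"),
                            qc = qc_thresholds(),
                            assignment = assignment_thresholds(),
                            locus_class = locus_class_thresholds(),
                            window_bp = 1e7, segment_bp = 5e4,
                            ld_max_dist_bp = 1e6, ld_threshold_r2 = 0.1,
                            block_max_span_bp = 5e5, tag_r2_min = 0.8,
                            K_values = 1:6, n_restarts = 5, cv_folds = 5,
                            min_group_lines = 10, supergroups = NULL,
                            seed = 1L) {
  if (is.null(format)) {
    format <- if (inherits(input, "sim_config")) "sim"
    else if (grepl("\\.vcf(\\.gz)?$", input)) "vcf"
    else "hapmap"
  }
  structure(as.list(environment()), class = "pipeline_config")
}

.stage_log <- function(log_path, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  cat(line, "\n", file = log_path, append = TRUE)
}

.write_tsv <- function(x, path) {
  is_list <- vapply(x, is.list, TRUE)
  x[is_list] <- lapply(x[is_list], vapply, paste, "", collapse = ",")
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full population-structure pipeline
#'
#' Stages, in order: load (or simulate) the panel; locus QC; diversity
#' summaries and tracks; LD segment map and decay; haplotype blocks and
#' tagSNPs on the het-masked panel; kinship; admixture fits over the K
#' grid with masking cross-validation to pick K; heterotic-group
#' assignment (validated against indicator lines when the registry has
#' any); pairwise Fst and UPGMA tree of the inferred groups;
#' group-specific locus classification for the two largest groups; PCA.
#' The admixture, Fst and assignment stages run on the tagSNP subset.
#' Every stage writes a TSV artifact under `cfg$out_dir` and appends to
#' `run_log.txt`; a failing stage aborts with a stage-labelled error.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with every stage result (`panel`, `qc`,
#'   `diversity`, `ld`, `blocks`, `kinship`, `cv`, `fit`, `assignments`,
#'   `fst`, `tree`, `group_loci`, `pca`, `artifacts`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  cat("", file = log_path)
  art <- character(0)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
    .stage_log(log_path, name,
               sprintf("done in %.1fs", as.numeric(Sys.time() - t0,
                                                   units = "secs")))
    res
  }

  panel <- stage("load", {
    if (cfg$format == "sim") simulate_panel(cfg$input)
    else if (cfg$format == "vcf") {
      if (!file.exists(cfg$input)) stop("input not found: ", cfg$input)
      read_vcf(cfg$input)
    } else {
      if (!file.exists(cfg$input)) stop("input not found: ", cfg$input)
      read_hapmap(cfg$input)
    }
  })

  qc <- stage("qc", qc_filter(panel$genotypes, panel$map, cfg$qc))
  .stage_log(log_path, "qc",
             sprintf("%d of %d loci retained", sum(qc$keep),
                     length(qc$keep)))
  art["qc_report"] <- .write_tsv(qc$report,
                                 file.path(cfg$out_dir, "qc_report.tsv"))
  G <- qc$genotypes; map <- qc$map

  div <- stage("diversity", {
    list(summary = panel_summary(G, map),
         gd_track = windowed_gd(G, map, cfg$window_bp),
         density = snp_density_track(map),
         adjacent = adjacent_distances(map))
  })
  art["diversity"] <- .write_tsv(div$summary,
                                 file.path(cfg$out_dir, "diversity.tsv"))
  art["gd_track"] <- .write_tsv(div$gd_track,
                                file.path(cfg$out_dir, "gd_track.tsv"))
  art["density"] <- .write_tsv(div$density,
                               file.path(cfg$out_dir, "snp_density.tsv"))
  art["distance_hist"] <- .write_tsv(
    div$adjacent$histogram, file.path(cfg$out_dir, "adjacent_distances.tsv"))

  ld <- stage("ld", {
    list(segments = segment_ld_map(G, map, cfg$segment_bp),
         decay = ld_decay(G, map, cfg$ld_max_dist_bp, cfg$ld_threshold_r2,
                          by_chrom = TRUE))
  })
  art["ld_segments"] <- .write_tsv(ld$segments,
                                   file.path(cfg$out_dir, "ld_segments.tsv"))
  art["ld_decay"] <- .write_tsv(ld$decay$curve,
                                file.path(cfg$out_dir, "ld_decay.tsv"))

  masked <- stage("mask", subgroup_missing_mask(G, map))
  blocks <- stage("blocks", haplotype_blocks(masked$genotypes, masked$map,
                                             max_span_bp = cfg$block_max_span_bp,
                                             r2_min = cfg$tag_r2_min))
  .stage_log(log_path, "blocks",
             sprintf("%d blocks, %d tag loci", nrow(blocks$blocks),
                     length(blocks$tag_loci)))
  art["blocks"] <- .write_tsv(
    blocks$blocks[, c("chrom", "start_bp", "end_bp", "n_members", "n_tags",
                      "tags")],
    file.path(cfg$out_dir, "blocks.tsv"))
  writeLines(blocks$tag_loci, file.path(cfg$out_dir, "tag_loci.txt"))
  art["tags"] <- file.path(cfg$out_dir, "tag_loci.txt")

  kin <- stage("kinship", kinship_matrix(G))
  khist <- kinship_histogram(kin)
  art["kinship_hist"] <- .write_tsv(
    khist$histogram, file.path(cfg$out_dir, "kinship_histogram.tsv"))
  write.table(round(kin$values, 6),
              file.path(cfg$out_dir, "kinship.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  art["kinship"] <- file.path(cfg$out_dir, "kinship.tsv")

  # tagSNP subset drives structure, assignment and Fst
  Gt <- G[, intersect(blocks$tag_loci, colnames(G)), drop = FALSE]
  cv <- stage("cv", cv_select_k(Gt, cfg$K_values, seed = cfg$seed,
                                n_folds = cfg$cv_folds))
  art["cv"] <- .write_tsv(cv$table, file.path(cfg$out_dir, "cv_error.tsv"))
  .stage_log(log_path, "cv", sprintf("best K = %d", cv$best_K))

  fit <- stage("admixture", fit_admixture(Gt, cv$best_K, seed = cfg$seed,
                                          n_restarts = cfg$n_restarts))
  write_q_matrix(fit$Q, file.path(cfg$out_dir, "fit.Q"))
  write_p_matrix(fit$P, file.path(cfg$out_dir, "fit.P"))
  art["Q"] <- file.path(cfg$out_dir, "fit.Q")

  # biological group names come from indicator lines where available
  has_ind <- any(!is.na(panel$lines$known_group))
  if (has_ind) {
    named <- name_groups_by_indicators(fit$Q, panel$lines)
    fit$Q <- named$Q
    rownames(fit$P) <- colnames(named$Q)
  }
  asg <- stage("assignment", assign_groups(fit$Q, cfg$assignment))
  conc <- if (has_ind) indicator_concordance(asg, panel$lines) else NULL
  if (!is.null(conc))
    .stage_log(log_path, "assignment",
               sprintf("indicator concordance %.3f", conc$fraction))
  art["assignments"] <- .write_tsv(
    cbind(asg, round(fit$Q[match(asg$line, rownames(fit$Q)), , drop = FALSE],
                     4)),
    file.path(cfg$out_dir, "assignments.tsv"))
  shares <- group_shares(asg, cfg$supergroups)
  art["shares"] <- .write_tsv(shares$para_with_base,
                              file.path(cfg$out_dir, "group_shares.tsv"))

  fst <- stage("fst", if (fit$K >= 2) fst_matrix(fit$P) else NULL)
  tree <- NULL
  if (!is.null(fst)) {
    write.table(round(fst, 4), file.path(cfg$out_dir, "fst_matrix.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    art["fst"] <- file.path(cfg$out_dir, "fst_matrix.tsv")
    tree <- fst_tree(fst)
    ape::write.tree(tree, file.path(cfg$out_dir, "fst_tree.nwk"))
    art["tree"] <- file.path(cfg$out_dir, "fst_tree.nwk")
  }

  gl <- stage("grouploci", {
    sizes <- table(asg$base_group[asg$base_group != "Mixed"])
    big <- names(sort(sizes, decreasing = TRUE))
    big <- big[seq_len(min(2, length(big)))]
    if (length(big) == 2 && all(sizes[big] >= cfg$min_group_lines)) {
      gf <- group_freqs(G, asg, big, cfg$min_group_lines)
      cls <- classify_loci(gf$freqs[1, ], gf$freqs[2, ], cfg$locus_class)
      dt <- diff_table(gf$freqs[1, ], gf$freqs[2, ], map)
      list(groups = big, freqs = gf, classes = cls, diff = dt,
           counts = class_count_table(cls, map))
    } else NULL
  })
  if (!is.null(gl)) {
    art["group_loci"] <- .write_tsv(gl$counts,
                                    file.path(cfg$out_dir,
                                              "group_locus_counts.tsv"))
    art["diff_table"] <- .write_tsv(gl$diff,
                                    file.path(cfg$out_dir,
                                              "freq_diff_table.tsv"))
  }

  pca <- stage("pca", pca_coordinates(G, n_components = 5))
  art["pca"] <- .write_tsv(
    data.frame(line = rownames(G), round(pca$scores, 6)),
    file.path(cfg$out_dir, "pca_coordinates.tsv"))

  invisible(list(panel = panel, qc = qc, diversity = div, ld = ld,
                 blocks = blocks, kinship = kin,
                 kinship_histogram = khist, cv = cv, fit = fit,
                 assignments = asg, indicator = conc, shares = shares,
                 fst = fst, tree = tree, group_loci = gl, pca = pca,
                 artifacts = art))
}
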