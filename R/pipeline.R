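## End-to-end orchestration: simulate -> histology -> correlation ->
## metabolic contextualization -> discriminative flux -> lipidomics,
## from one validated configuration, with per-stage JSON manifests and a
## collated recovery report.

#' Default pipeline configuration
#'
#' Analysis thresholds default to the study conventions: 512-pixel
#' patches with a 0.5 tissue filter, correlation screen at r > 0.7 and
#' q < 0.05, biomarker screen at p < 0.01, TAC comparisons at p < 0.05,
#' objective fraction 1.0, 50-500 flux samples, 100 random-forest splits
#' at an 80/20 ratio with a 0.60 accuracy gate and top-10 extraction.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    synthetic = list(
      n_disease = 6L, n_control = 6L, image_size = 256L,
      n_genes = 200L, n_planted_genes = 3L, planted_r = 0.95,
      network_template = "coupled_pathways", n_units = 3L,
      flux_shift = 4, transcript_noise_cv = 0.2,
      lipid_classes = list(PC = 12L, LPC = 8L, PE = 10L, TG = 12L,
                           SM = 8L, CE = 6L),
      lipid_shifts = list(PC = 1),
      lipid_n_per_group = 10L,
      biomarker = list(name = "CRP", target_r = 0.9),
      tac = list(name = "EAEC", flip_rate = 0.05),
      write_images = FALSE),
    histology = list(patch_size = 512L, tissue_threshold = 0.5,
                     input_size = 64L, channels = c(8L, 16L),
                     feature_width = 16L, epochs = 18L, lr = 0.02,
                     batch_size = 16L),
    screens = list(r_min = 0.7, q_max = 0.05, biomarker_p = 0.01,
                   tac_p = 0.05),
    metabolic = list(objective_fraction = 1.0, n_samples = 50L,
                     budget_relax = 0.01),
    discriminative = list(n_splits = 100L, train_fraction = 0.8,
                          top_k = 10L, accuracy_min = 0.60),
    lipidomics = list(n_permutations = 1000L, pseudocount = 1),
    stages = list(histology = TRUE, correlation = TRUE,
                  metabolic = TRUE, lipidomics = TRUE))
}

#' Default desk-scale synthetic run configuration
#'
#' [default_config()] with the patch size lowered to 64 pixels to match
#' the 256-pixel synthetic slides (every analysis threshold is
#' unchanged).
#'
#' @return nested configuration list.
#' @export
default_synthetic_config <- function() {
  cfg <- default_config()
  cfg$histology$patch_size <- 64L
  cfg
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a file path (YAML or JSON) or a nested list; unknown keys are
#' rejected, missing keys filled from [default_config()], and value
#' constraints checked. All problems are reported together.
#'
#' @param config path or list (empty list gives the full default).
#' @return the normalized configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config) else jsonlite::read_json(config, simplifyVector = TRUE)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop_invalid("config must be a list or a file path")
  defaults <- default_config()
  errors <- character(0)
  check_keys <- function(x, template, path) {
    for (nm in names(x)) {
      if (!nm %in% names(template)) {
        errors <<- c(errors, sprintf("unknown key: %s%s", path, nm))
      } else if (is.list(template[[nm]]) && !is.null(names(template[[nm]])) &&
                 is.list(x[[nm]])) {
        check_keys(x[[nm]], template[[nm]], paste0(path, nm, "$"))
      }
    }
  }
  check_keys(config, defaults, "")
  merged <- utils::modifyList(defaults, config)
  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  chk(is.numeric(merged$seed) && merged$seed >= 0 &&
        merged$seed == floor(merged$seed), "seed must be a nonnegative integer")
  chk(merged$screens$r_min > 0 && merged$screens$r_min < 1,
      "screens$r_min must be in (0, 1)")
  chk(merged$screens$q_max > 0 && merged$screens$q_max <= 1,
      "screens$q_max must be in (0, 1]")
  chk(merged$metabolic$objective_fraction > 0 &&
        merged$metabolic$objective_fraction <= 1,
      "metabolic$objective_fraction must be in (0, 1]")
  chk(merged$discriminative$train_fraction > 0 &&
        merged$discriminative$train_fraction < 1,
      "discriminative$train_fraction must be in (0, 1)")
  chk(merged$histology$tissue_threshold >= 0 &&
        merged$histology$tissue_threshold <= 1,
      "histology$tissue_threshold must be in [0, 1]")
  if (length(errors))
    stop_invalid("invalid configuration:\n  - %s", paste(errors, collapse = "\n  - "))
  merged
}

write_manifest <- function(dir, stage, params, files) {
  existing <- files[file.exists(files)]
  manifest <- list(stage = stage, params = params,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   files = as.list(stats::setNames(
                     as.character(tools::md5sum(existing)), basename(existing))))
  jsonlite::write_json(manifest, file.path(dir, sprintf("%s_manifest.json", stage)),
                       auto_unbox = TRUE, digits = NA)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic pipeline
#'
#' Simulates a cohort with planted ground truth, trains the patch
#' classifier, runs the correlation screens, builds per-subject
#' contextualized metabolic models with flux sampling and random-forest
#' reaction extraction, runs the lipid enrichment analysis, and collates
#' a recovery report. Every stage writes its outputs and a JSON manifest
#' (parameters, seed, file checksums) under `out_dir`; a stage failure
#' halts downstream stages but preserves upstream artifacts.
#'
#' @param config configuration accepted by [validate_config()]
#'   (default: [default_synthetic_config()]).
#' @param out_dir output directory (created; default a tempdir run
#'   folder).
#' @return (invisibly) list with per-stage results and the `report`.
#' @export
run_pipeline <- function(config = default_synthetic_config(),
                         out_dir = file.path(tempdir(), "eedomics_run")) {
  cfg <- validate_config(config)
  if (cfg$synthetic$image_size < 2 * cfg$histology$patch_size)
    stop_invalid(paste0("synthetic$image_size (%d) must be at least twice ",
                        "histology$patch_size (%d) for a synthetic run"),
                 cfg$synthetic$image_size, cfg$histology$patch_size)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  report <- list()
  res <- list(config = cfg)

  ## --- simulate -------------------------------------------------------------
  sy <- cfg$synthetic
  cohort <- generate_wsi_cohort(sy$n_disease, sy$n_control, sy$image_size,
                                seed = seed)
  if (isTRUE(sy$write_images)) write_wsi_cohort(cohort, file.path(out_dir, "slides"))
  net <- generate_toy_network(sy$network_template, list(n_units = sy$n_units))
  write_network(net, file.path(out_dir, "network.json"), "json")
  planted_flux <- list()
  if (sy$network_template == "coupled_pathways" && sy$flux_shift > 1) {
    for (k in seq_len(sy$n_units)) {
      planted_flux <- c(planted_flux, list(
        list(reaction_id = sprintf("R%d_hi", k), group_mean_shift = sy$flux_shift,
             direction = "up_in_disease"),
        list(reaction_id = sprintf("R%d_lo", k), group_mean_shift = sy$flux_shift,
             direction = "down_in_disease")))
    }
  }
  ta <- generate_transcript_abundances(net, sy$n_disease, planted_flux,
                                       noise_cv = sy$transcript_noise_cv,
                                       seed = seed)
  lip <- generate_lipidomics(sy$lipid_n_per_group,
                             unlist(sy$lipid_classes),
                             unlist(sy$lipid_shifts), seed = seed)
  truth <- list(planted_flux_reactions = vapply(planted_flux, `[[`, "", "reaction_id"),
                planted_lipid_shifts = sy$lipid_shifts)
  write_tsv(data.frame(species = rownames(lip$intensities),
                       lip$intensities, check.names = FALSE),
            file.path(out_dir, "lipidomics.tsv"))
  write_manifest(out_dir, "simulate",
                 list(seed = seed, synthetic = sy),
                 file.path(out_dir, c("network.json", "lipidomics.tsv")))

  ## --- histology ------------------------------------------------------------
  if (!isTRUE(cfg$stages$histology))
    stop_invalid("the histology stage is required by all downstream stages")
  hi <- cfg$histology
  patches <- unlist(lapply(cohort, extract_patches,
                           patch_size = hi$patch_size,
                           tissue_threshold = hi$tissue_threshold),
                    recursive = FALSE)
  model <- train_classifier(patches, cnn_config(
    input_size = hi$input_size, channels = hi$channels,
    feature_width = hi$feature_width, epochs = hi$epochs, lr = hi$lr,
    batch_size = hi$batch_size, seed = substream_seed(seed, 40L)))
  val_subjects <- model$split$subject[model$split$role == "validation"]
  ev <- evaluate(model, patches[vapply(patches, function(p) p$parent, "") %in%
                                  val_subjects])
  dis_patches <- Filter(function(p) identical(p$label, "disease") &&
                          !is.null(p$mask) && sum(p$mask) > 0, patches)
  hits <- vapply(dis_patches, function(p) {
    g <- gradcam(model, p$pixels, "disease")
    h <- g$heat; tot <- sum(h)
    if (tot == 0) return(FALSE)
    cr <- sum(row(h) * h) / tot; cc <- sum(col(h) * h) / tot
    mk <- which(p$mask == 1, arr.ind = TRUE)
    min(sqrt((mk[, 1] - cr)^2 + (mk[, 2] - cc)^2)) <= 0.1 * nrow(h)
  }, TRUE)
  res$histology <- list(model = model, evaluation = ev,
                        gradcam_hit_rate = mean(hits))
  report$histology <- list(
    held_out_patch_accuracy = ev$accuracy,
    per_class_accuracy = as.list(ev$per_class_accuracy),
    gradcam_localization_rate = mean(hits))
  write_tsv(patch_manifest(patches), file.path(out_dir, "patches.tsv"))
  write_tsv(model$split, file.path(out_dir, "split_manifest.tsv"))
  write_manifest(out_dir, "histology", hi,
                 file.path(out_dir, c("patches.tsv", "split_manifest.tsv")))

  ## --- correlation screens --------------------------------------------------
  if (isTRUE(cfg$stages$correlation)) {
    reps <- patient_representations(model, cohort, hi$patch_size,
                                    hi$tissue_threshold)
    vars <- apply(reps, 2, stats::var)
    feat_idx <- order(-vars)[seq_len(cfg$synthetic$n_planted_genes)]
    planted_genes <- lapply(seq_along(feat_idx), function(i)
      list(gene_id = sprintf("planted_gene_%02d", i),
           feature_index = feat_idx[i], target_r = sy$planted_r))
    expr <- generate_expression(reps, sy$n_genes, planted_genes, seed = seed)
    screen <- correlate_gene_features(expr, reps)
    pairs <- filter_pairs(screen, cfg$screens$r_min, cfg$screens$q_max)
    ranking <- genes_by_feature_count(pairs)
    clin <- generate_clinical_table(
      nrow(reps),
      planted_assoc = list(
        biomarker = list(name = sy$biomarker$name,
                         feature_index = feat_idx[1],
                         target_r = sy$biomarker$target_r),
        tac = list(name = sy$tac$name, feature_index = feat_idx[1],
                   flip_rate = sy$tac$flip_rate)),
      seed = seed, reps = reps)
    bio <- correlate_biomarkers(clin$biomarkers, reps, cfg$screens$biomarker_p)
    tac <- compare_tac(clin$tac, reps, cfg$screens$tac_p)
    res$correlation <- list(reps = reps, screen = screen, pairs = pairs,
                            ranking = ranking, biomarkers = bio, tac = tac,
                            expression = expr)
    report$correlation <- list(
      planted_genes = vapply(planted_genes, `[[`, "", "gene_id"),
      recovered_genes = unique(pairs$entity),
      planted_recovered = all(vapply(planted_genes, `[[`, "", "gene_id") %in%
                                pairs$entity),
      biomarker_flagged = unique(bio$entity[bio$flagged]),
      planted_biomarker_flagged = sy$biomarker$name %in% bio$entity[bio$flagged],
      tac_flagged = unique(tac$entity[tac$flagged]),
      planted_tac_flagged = sy$tac$name %in% tac$entity[tac$flagged])
    write_tsv(screen, file.path(out_dir, "gene_feature_screen.tsv"))
    write_tsv(bio, file.path(out_dir, "biomarker_screen.tsv"))
    write_tsv(tac, file.path(out_dir, "tac_screen.tsv"))
    write_manifest(out_dir, "correlation", cfg$screens,
                   file.path(out_dir, c("gene_feature_screen.tsv",
                                        "biomarker_screen.tsv", "tac_screen.tsv")))
  }

  ## --- metabolic contextualization + discriminative reactions ---------------
  if (isTRUE(cfg$stages$metabolic)) {
    me <- cfg$metabolic
    mats <- lapply(colnames(ta$abundances), function(s) {
      ab <- map_abundance_to_reactions(net, ta$abundances[, s])
      cm <- contextualize(net, ab, me$objective_fraction,
                          budget_relax = me$budget_relax,
                          provenance = list(subject = s, group = ta$groups[[s]]))
      suppressWarnings(sample_fluxes(
        cm, me$n_samples,
        seed = substream_seed(seed, 50L + match(s, colnames(ta$abundances)))))
    })
    ds <- assemble_dataset(mats)
    dc <- cfg$discriminative
    rfrep <- rf_classify_splits(ds, dc$n_splits, dc$train_fraction,
                                dc$top_k, seed = substream_seed(seed, 60L))
    top <- extract_top_reactions(rfrep, dc$accuracy_min, dc$top_k)
    fams <- group_by_subsystem(top$reaction, net)
    mwtab <- do.call(rbind, lapply(top$reaction, function(r) {
      cg <- compare_groups(ds, r)
      data.frame(reaction = r, U = cg$U, p = cg$p,
                 median_disease = cg$medians[["disease"]],
                 median_control = cg$medians[["control"]])
    }))
    res$metabolic <- list(dataset = ds, report = rfrep, top = top,
                          families = fams, group_tests = mwtab)
    report$metabolic <- list(
      planted_reactions = truth$planted_flux_reactions,
      top_reactions = top$reaction,
      planted_in_top = all(truth$planted_flux_reactions %in% top$reaction),
      median_split_accuracy = stats::median(rfrep$splits$accuracy),
      families = stats::setNames(as.list(fams$family), fams$reaction))
    write_tsv(rfrep$splits, file.path(out_dir, "rf_splits.tsv"))
    write_tsv(top, file.path(out_dir, "top_reactions.tsv"))
    write_tsv(mwtab, file.path(out_dir, "reaction_group_tests.tsv"))
    write_manifest(out_dir, "metabolic", c(me, dc),
                   file.path(out_dir, c("rf_splits.tsv", "top_reactions.tsv",
                                        "reaction_group_tests.tsv")))
  }

  ## --- lipidomics -----------------------------------------------------------
  if (isTRUE(cfg$stages$lipidomics)) {
    norm <- normalize_intensities(lip$intensities, cfg$lipidomics$pseudocount)
    fc <- fold_changes(norm, lip$groups)
    enr <- suppressWarnings(lsea(fc, n_permutations = cfg$lipidomics$n_permutations,
                                 seed = substream_seed(seed, 70L)))
    pc <- lipid_pca(norm)
    res$lipidomics <- list(normalized = norm, fold_changes = fc,
                           lsea = enr, pca = pc)
    planted_cls <- names(sy$lipid_shifts)
    report$lipidomics <- list(
      planted_classes = sy$lipid_shifts,
      lsea = enr,
      planted_detected = all(vapply(planted_cls, function(cl) {
        row <- enr[enr$lipid_class == cl, ]
        nrow(row) == 1L && row$p_permutation < 0.05 &&
          row$direction == (if (sy$lipid_shifts[[cl]] > 0) "up" else "down")
      }, TRUE)),
      pc1_pc2_explained = pc$explained_variance[1:2])
    write_tsv(fc, file.path(out_dir, "lipid_fold_changes.tsv"))
    write_tsv(enr, file.path(out_dir, "lsea.tsv"))
    write_manifest(out_dir, "lipidomics", cfg$lipidomics,
                   file.path(out_dir, c("lipid_fold_changes.tsv", "lsea.tsv")))
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$report <- report
  res$out_dir <- out_dir
  invisible(res)
}
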