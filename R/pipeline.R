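## Pipeline orchestration: a strict YAML config drives the stages
## simulate -> methylome -> states -> contacts -> genome3d -> loops,
## with structured logging and a deterministic manifest.

.stage_order <- c("simulate", "methylome", "states", "contacts",
                  "genome3d", "loops")

.schema <- list(
  top = c("stages", "out_dir", "seed", "log_level", "sim", "methylome",
          "states", "contacts", "genome3d", "loops"),
  methylome = c("hypo_cutoff", "coverage_min", "coverage_max", "top_k",
                "require_3c"),
  states = c("pos_cutoff", "neg_cutoff", "n_components", "n_clusters",
             "k", "log2fc_delta", "log2fc_noise_sd", "log2fc_genes"),
  contacts = c("standardize", "insulation_window", "insulation_min_depth",
               "boundary_window"),
  genome3d = c("resolution", "n_quantiles", "p_bins", "q_bins",
               "min_chrom_bins", "min_missing"),
  loops = c("pad", "dmin", "dmax", "max_candidates"))

.defaults <- list(
  methylome = list(hypo_cutoff = 0.9, coverage_min = 500,
                   coverage_max = 3000, top_k = 20000, require_3c = TRUE),
  states = list(pos_cutoff = 2.5, neg_cutoff = -2.5, n_components = 50,
                n_clusters = 2, k = 3, log2fc_delta = 2,
                log2fc_noise_sd = 0.1, log2fc_genes = 200),
  contacts = list(standardize = TRUE, insulation_window = 10,
                  insulation_min_depth = 0.1, boundary_window = 1e6),
  genome3d = list(resolution = 1e5, n_quantiles = 10, p_bins = 50,
                  q_bins = 50, min_chrom_bins = 50, min_missing = 10),
  loops = list(pad = 7, dmin = 5, dmax = 500, max_candidates = 500))

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown configuration key '%s' in %s", bad[1], where),
         call. = FALSE)
}

.load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
    if (is.null(config) || !is.list(config))
      stop("config parse error: file is empty or not a YAML mapping",
           call. = FALSE)
  }
  config
}

#' Validate a pipeline configuration without executing it
#'
#' Checks the strict schema (unknown keys rejected, naming the key), the
#' stage list, and cross-stage dependencies: every requested stage's inputs
#' must be producible by an earlier requested stage, and the 3D stage needs
#' a centromere position for every chromosome.
#'
#' @param config path to a YAML file, or an already-parsed config list.
#' @return list with `valid` (logical) and `errors` (character vector).
#' @export
validateRunConfig <- function(config) {
  errors <- character()
  cfg <- tryCatch(.load_config(config), error = function(e) conditionMessage(e))
  if (is.character(cfg)) return(list(valid = FALSE, errors = cfg))
  res <- tryCatch({
    .check_keys(cfg, .schema$top, "top level")
    for (blk in c("methylome", "states", "contacts", "genome3d", "loops"))
      if (!is.null(cfg[[blk]]))
        .check_keys(cfg[[blk]], .schema[[blk]], paste0("block '", blk, "'"))
    stages <- cfg$stages
    if (is.null(stages)) stages <- .stage_order
    bad <- setdiff(stages, .stage_order)
    if (length(bad)) stop("unknown stage '", bad[1], "'", call. = FALSE)
    sim_cfg <- do.call(simConfig, c(cfg$sim,
      if (!is.null(cfg$seed) && is.null(cfg$sim$seed))
        list(seed = cfg$seed)))
    for (st in setdiff(stages, "simulate"))
      if (!"simulate" %in% stages)
        stop("stage '", st, "' depends on stage 'simulate', which is not ",
             "enabled and whose outputs are not available", call. = FALSE)
    if ("genome3d" %in% stages) {
      missing_cen <- setdiff(names(sim_cfg$chrom_lengths),
                             names(sim_cfg$centromeres))
      if (length(missing_cen))
        stop("genome3d stage enabled but centromere position missing for ",
             paste(missing_cen, collapse = ", "), call. = FALSE)
    }
    TRUE
  }, error = function(e) conditionMessage(e))
  if (is.character(res)) errors <- res
  list(valid = !length(errors), errors = errors)
}

.log_stage <- function(level, stage, t0, ...) {
  if (identical(level, "quiet")) return(invisible())
  message(sprintf("[%s] elapsed=%.1fs %s", stage,
                  as.numeric(proc.time()[3] - t0), paste(..., sep = " ")))
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the requested stages in dependency order on a synthetic cohort,
#' writes per-stage result tables under `out_dir`, and records a manifest
#' (parameters, package version, md5 of every written file). Rerunning with
#' the same configuration produces byte-identical outputs and manifest
#' hashes.
#'
#' @param config path to a YAML config, or a config list. Recognized
#'   top-level keys: `stages`, `out_dir`, `seed`, `log_level`, `sim` (any
#'   [simConfig()] field) and per-stage blocks `methylome`, `states`,
#'   `contacts`, `genome3d`, `loops` whose keys default to the
#'   study-standard constants (hypo-score cutoff 0.9, k = 3 subgroups,
#'   state-score cutoffs +/-2.5, 10 PC1 quantiles, deletion threshold 10
#'   missing pseudo-bulks, loop distance range 5-500 bins with +/-7-bin
#'   blacklist padding).
#' @param seed optional override of the config seed.
#' @param out_dir optional override of the output directory.
#' @return (invisibly) a list of in-memory stage results plus `manifest`.
#' @export
runPipeline <- function(config, seed = NULL, out_dir = NULL) {
  cfg <- .load_config(config)
  chk <- validateRunConfig(cfg)
  if (!chk$valid) stop("invalid configuration: ", chk$errors[1],
                       call. = FALSE)
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$out_dir)) cfg$out_dir <- tempfile("epistate3c_run_")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_level <- if (is.null(cfg$log_level)) "info" else cfg$log_level
  stages <- if (is.null(cfg$stages)) .stage_order else
    .stage_order[.stage_order %in% cfg$stages]
  par <- .defaults
  for (blk in names(.defaults))
    if (!is.null(cfg[[blk]])) par[[blk]][names(cfg[[blk]])] <- cfg[[blk]]
  sim_args <- cfg$sim
  if (!is.null(cfg$seed) && is.null(sim_args$seed))
    sim_args$seed <- cfg$seed
  sim_cfg <- do.call(simConfig, sim_args)
  R <- list(config = sim_cfg)
  files <- character()
  emit <- function(obj, name) {
    path <- file.path(cfg$out_dir, name)
    if (is.data.frame(obj))
      utils::write.table(obj, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    else if (is.matrix(obj))
      utils::write.table(obj, path, sep = "\t", quote = FALSE)
    files <<- c(files, path)
    path
  }

  for (stage in stages) {
    t0 <- proc.time()[3]
    ok <- tryCatch({
      switch(stage,
        simulate = {
          sim <- simulateCohort(sim_cfg)
          R$meta <- sim$meta; R$truth <- sim$truth
          emit(sim$meta, "cell_meta.tsv")
          writeTruthJSON(sim$truth, file.path(cfg$out_dir, "truth.json"))
          files <- c(files, file.path(cfg$out_dir, "truth.json"))
          R$methyl <- simulateMethylome(sim$meta, sim$truth, sim_cfg)
          R$contacts <- simulateContacts(sim$meta, sim$truth, sim_cfg)
          R$bcalls <- simulateBoundaryCalls(sim$meta, sim$truth, sim_cfg)
          .log_stage(log_level, stage, t0, "cells:", nrow(sim$meta))
        },
        methylome = {
          qc <- qcFilter(R$meta, require_3c = par$methylome$require_3c)
          R$qc <- qc
          gl <- globalLevels(R$methyl, R$meta,
                             c("cell_type", "region", "disease"))
          emit(gl, "global_levels.tsv")
          R$cell_levels <- cellGlobalLevels(R$methyl)
          scores <- hypoScore(R$methyl, "CG")
          R$hypo_binary <- binarizeScores(scores, par$methylome$hypo_cutoff)
          ## bin-level association of per-sample mean CG fraction with AD
          mc <- SummarizedExperiment::assay(R$methyl, "mc_CG")
          cov <- SummarizedExperiment::assay(R$methyl, "cov_CG")
          skey <- paste(R$meta$donor, R$meta$region, sep = "_")
          usamp <- unique(skey)
          agg <- function(m) sapply(usamp, function(s)
            rowSums(m[, skey == s, drop = FALSE]))
          vals <- agg(mc) / pmax(agg(cov), 1)
          rownames(vals) <- sprintf("bin%04d", seq_len(nrow(vals)))
          smeta <- R$meta[match(usamp, skey),
                          c("donor", "region", "disease", "sex", "age",
                            "instrument")]
          vals_bc <- batchCorrect(vals, smeta)
          R$bin_assoc <- fitFeatureModel(vals_bc, smeta)
          emit(R$bin_assoc, "bin_association.tsv")
          R$dm_bins <- selectByCutoffs(R$bin_assoc, "diseaseAD")
          .log_stage(log_level, stage, t0, "qc pass:", length(qc$pass),
                     "| DM bins:", length(R$dm_bins))
        },
        states = {
          norm <- normalizeInstruments(R$cell_levels, R$meta,
                                       R$truth@shared_libraries)
          strata <- ifelse(R$meta$cell_type[match(norm$cell_id,
                                                  R$meta$cell_id)] %in%
                           sim_cfg$neuron_cell_types, "neuron", "non-neuron")
          R$subgroups <- kmeansSubgroups(norm, strata, k = par$states$k,
                                         seed = sim_cfg$seed)
          emit(R$subgroups, "subgroups.tsv")
          R$ratio_assoc <- subgroupRatioAssociation(R$subgroups, R$meta)
          emit(R$ratio_assoc, "subgroup_association.tsv")
          subtypes <- as.vector(outer(sim_cfg$cell_types,
                                      paste0("g", 0:2), paste, sep = ":"))
          planted <- stats::setNames(
            ifelse(grepl(":g0$", subtypes), "Stressed", "Homeostatic"),
            subtypes)
          lfc <- simulateLog2fcTensor(subtypes, planted,
                                      n_genes = par$states$log2fc_genes,
                                      delta = par$states$log2fc_delta,
                                      noise_sd = par$states$log2fc_noise_sd,
                                      seed = sim_cfg$seed)
          cl <- subtypeSimilarityCluster(lfc, par$states$n_components,
                                         par$states$n_clusters)
          R$subtype_clusters <- cl
          R$state_labels <- labelStateClusters(
            cl, stats::setNames(as.numeric(grepl(":g0$", cl$subtypes)),
                                cl$subtypes))
          R$planted_subtype_state <- planted
          emit(data.frame(subtype = names(R$state_labels),
                          state = unname(R$state_labels)),
               "subtype_states.tsv")
          .log_stage(log_level, stage, t0, "subtypes:", length(subtypes))
        },
        contacts = {
          prof <- decayProfile(R$contacts)
          R$decay_profiles <- prof
          cs <- contactScore(prof)
          R$contact_scores <- cs$score
          R$short_long <- classifyShortLong(prof,
                                            par$contacts$standardize,
                                            seed = sim_cfg$seed)
          emit(data.frame(cell_id = rownames(prof), score = cs$score,
                          class = unname(R$short_long[rownames(prof)])),
               "contact_classes.tsv")
          dens <- boundaryDensity(R$bcalls, R$meta,
                                  window = par$contacts$boundary_window)
          cov <- meanCisLongPerSample(R$contacts, R$meta)
          R$boundary_density <- adjustBoundaryDensity(dens, cov)
          emit(R$boundary_density, "boundary_density.tsv")
          .log_stage(log_level, stage, t0, "cells:", nrow(prof))
        },
        genome3d = {
          res <- par$genome3d$resolution
          states <- R$truth@cells$state[match(R$meta$cell_id,
                                              R$truth@cells$cell_id)]
          m2 <- cbind(R$meta, state = states)
          pbs <- pseudoBulkGroups(R$contacts, m2,
                                  c("region", "cell_type", "state"), res)
          pbs <- lapply(pbs, function(g) lapply(g, balanceICE))
          R$pseudo_bulks <- pbs
          ## compartments on the pooled map, per chromosome
          pooled <- lapply(pseudoBulk(R$contacts, resolution = res),
                           balanceICE)
          gcs <- lapply(names(pooled), function(ch)
            syntheticGCTrack(sim_cfg, ch, res))
          names(gcs) <- names(pooled)
          R$pc1 <- lapply(names(pooled), function(ch)
            compartmentPc1(pooled[[ch]], gcs[[ch]]))
          names(R$pc1) <- names(pooled)
          pc1_df <- do.call(rbind, lapply(names(R$pc1), function(ch)
            cbind(chrom = ch, R$pc1[[ch]])))
          emit(pc1_df, "compartment_pc1.tsv")
          ## state saddles from state-pooled maps, shared PC1 ordering
          for (st in c("Homeostatic", "Stressed")) {
            cells <- R$meta$cell_id[states == st]
            sm <- lapply(pseudoBulk(R$contacts, cells, res), balanceICE)
            R[[paste0("saddle_", st)]] <-
              saddle(sm[names(R$pc1)], R$pc1,
                     n_quantiles = par$genome3d$n_quantiles)
          }
          R$saddle_ratio <- saddleStateRatio(R$saddle_Stressed,
                                             R$saddle_Homeostatic)
          emit(as.data.frame(R$saddle_ratio), "saddle_state_ratio.tsv")
          R$arm_average <- centromereAlignedAverage(
            pooled, sim_cfg$centromeres, resolution = res,
            p_bins = par$genome3d$p_bins, q_bins = par$genome3d$q_bins,
            min_chrom_bins = par$genome3d$min_chrom_bins)
          R$deletions <- detectPutativeDeletions(
            pbs, min_missing = par$genome3d$min_missing,
            chrom_lengths = sim_cfg$chrom_lengths)
          st_of <- stats::setNames(
            vapply(strsplit(names(pbs), "/"), function(x) x[3], ""),
            names(pbs))
          R$deletion_state_counts <- deletionStateCounts(R$deletions, st_of)
          writeDeletionsBED(R$deletions,
                            file.path(cfg$out_dir, "deletions.bed"),
                            file.path(cfg$out_dir, "deletions.tsv"))
          files <- c(files, file.path(cfg$out_dir, "deletions.bed"),
                     file.path(cfg$out_dir, "deletions.tsv"))
          .log_stage(log_level, stage, t0, "pseudo-bulks:", length(pbs),
                     "| deletions:", nrow(R$deletions))
        },
        loops = {
          res <- par$genome3d$resolution
          ch <- names(sim_cfg$chrom_lengths)[1]
          nb <- ceiling(sim_cfg$chrom_lengths[[ch]] / res)
          dt <- contactsTable(R$contacts)
          dt <- dt[dt$chrom1 == ch & dt$chrom2 == ch, ]
          dt$i <- pmin(floor((dt$pos1 - 1) / res) + 1, nb)
          dt$j <- pmin(floor((dt$pos2 - 1) / res) + 1, nb)
          lo <- pmin(dt$i, dt$j); dt$j <- pmax(dt$i, dt$j); dt$i <- lo
          per_cell <- dt[, .(n = .N), by = .(cell_id, i, j)]
          dis <- R$meta$disease[match(per_cell$cell_id, R$meta$cell_id)]
          accs <- lapply(c("AD", "Control"), function(gp) {
            pc <- per_cell[dis == gp]
            sx <- matrix(0, nb, nb); sx2 <- matrix(0, nb, nb)
            agg <- pc[, .(s = sum(n), s2 = sum(n^2)), by = .(i, j)]
            sx[cbind(agg$i, agg$j)] <- agg$s
            sx2[cbind(agg$i, agg$j)] <- agg$s2
            structure(list(sum_x = sx, sum_x2 = sx2,
                           n = sum(R$meta$disease == gp), label = gp),
                      class = "GroupContactAccumulator")
          })
          fs <- pixelFStatistic(accs)
          msk <- maskPixels(nb, pad = par$loops$pad,
                            dmin = par$loops$dmin, dmax = par$loops$dmax)
          cand <- candidatePixels(fs, msk)
          if (nrow(cand) > par$loops$max_candidates)
            cand <- cand[seq_len(par$loops$max_candidates), ]
          R$loop_candidates <- cbind(chrom = ch, cand)
          if (nrow(cand)) {
            skey <- paste(R$meta$donor, R$meta$region, sep = "_")
            usamp <- unique(skey)
            vals <- matrix(0, nrow(cand), length(usamp),
                           dimnames = list(
                             sprintf("%s:%d_%d", ch, cand$bin1, cand$bin2),
                             usamp))
            pk <- paste(per_cell$i, per_cell$j)
            ck <- paste(cand$bin1, cand$bin2)
            sk <- skey[match(per_cell$cell_id, R$meta$cell_id)]
            keep <- pk %in% ck
            agg <- per_cell[keep][, .(s = sum(n)),
                                  by = .(pix = pk[keep], samp = sk[keep])]
            ns <- table(skey)[usamp]
            vals[cbind(match(agg$pix, ck), match(agg$samp, usamp))] <- agg$s
            vals <- sweep(vals, 2, as.numeric(ns), "/")
            smeta <- R$meta[match(usamp, skey),
                            c("donor", "disease", "sex", "age")]
            R$loop_assoc <- loopCovariateRegression(vals, smeta)
            emit(R$loop_assoc, "loop_association.tsv")
          }
          emit(R$loop_candidates, "loop_candidates.tsv")
          .log_stage(log_level, stage, t0, "candidates:", nrow(cand))
        })
      TRUE
    }, error = function(e) {
      marker <- file.path(cfg$out_dir, paste0(stage, ".partial"))
      writeLines(conditionMessage(e), marker)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  manifest <- list(
    package = "epistate3c",
    version = as.character(utils::packageVersion("epistate3c")),
    seed = sim_cfg$seed, stages = stages,
    parameters = par,
    files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  R$manifest <- manifest
  invisible(R)
}
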