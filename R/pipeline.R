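# End-to-end orchestration: simulate or load two cohorts, QC, association
# (both adjustment modes), LD, the six PRS models (model1/2/3 x unadjusted/
# age-adjusted weights), evaluation on the held-out cohort, and a
# reproducibility manifest. Training and evaluation cohorts are kept
# separate by contract: weights are always estimated on the training cohort.

pipeline_schema <- list(
  top = c("seed", "out_dir", "simulate", "sim", "input", "qc", "association",
          "ld", "prs", "allow_single_cohort"),
  sim = c("n_cases_1", "n_controls_1", "n_cases_2", "n_controls_2",
          "block_r2", "missing_rate", "dropout_snps", "dropout_rate",
          "prevalence", "min_call_rate"),
  input = c("training", "evaluation", "manifest"),
  cohort = c("genotypes", "dialect", "phenotypes", "status_dialect"),
  qc = c("call_rate_threshold", "maf_threshold", "hwe_p_threshold",
         "hwe_method"),
  association = c("alpha"),
  ld = c("r2_threshold"),
  prs = c("missing_policy", "cutpoint_source")
)

#' Validate a pipeline configuration
#'
#' Schema-checks a configuration (YAML path or list): unknown keys are
#' rejected so typos never pass silently, thresholds must be in range, and
#' the training and evaluation cohorts must be distinct unless
#' `allow_single_cohort` is set.
#'
#' @param config path to a YAML file, or a named list.
#' @return `TRUE` if valid; otherwise a character vector of violations.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  v <- character()
  bad <- setdiff(names(config), pipeline_schema$top)
  if (length(bad)) v <- c(v, paste("unknown key(s):", paste(bad, collapse = ", ")))
  if (is.null(config$seed)) v <- c(v, "seed is required")
  if (is.null(config$out_dir)) v <- c(v, "out_dir is required")
  simulate <- isTRUE(config[["simulate"]])
  if (!simulate && is.null(config[["input"]])) {
    v <- c(v, "either simulate: true or an input section is required")
  }
  chk_range <- function(x, nm, lo, hi) {
    if (!is.null(x) && (!is.numeric(x) || x < lo || x > hi)) {
      paste0(nm, " must be in [", lo, ", ", hi, "]")
    }
  }
  for (sec in c("sim", "input", "qc", "association", "ld", "prs")) {
    s <- config[[sec]]
    if (is.null(s)) next
    bad <- setdiff(names(s), pipeline_schema[[sec]])
    if (length(bad)) {
      v <- c(v, paste0("unknown key(s) in ", sec, ": ",
                       paste(bad, collapse = ", ")))
    }
  }
  v <- c(v,
    chk_range(config[["qc"]]$call_rate_threshold, "qc.call_rate_threshold", 0, 1),
    chk_range(config[["qc"]]$maf_threshold, "qc.maf_threshold", 0, 0.5),
    chk_range(config[["qc"]]$hwe_p_threshold, "qc.hwe_p_threshold", 0, 1),
    chk_range(config[["association"]]$alpha, "association.alpha", 0, 1),
    chk_range(config[["ld"]]$r2_threshold, "ld.r2_threshold", 0, 1),
    chk_range(config[["sim"]]$block_r2, "sim.block_r2", 0, 0.999),
    chk_range(config[["sim"]]$missing_rate, "sim.missing_rate", 0, 0.999))
  if (!is.null(config[["prs"]]$missing_policy) &&
      !config[["prs"]]$missing_policy %in% c("impute_control_freq", "renormalize")) {
    v <- c(v, "prs.missing_policy must be impute_control_freq or renormalize")
  }
  if (!is.null(config[["prs"]]$cutpoint_source) &&
      !config[["prs"]]$cutpoint_source %in% c("controls", "combined")) {
    v <- c(v, "prs.cutpoint_source must be controls or combined")
  }
  if (!simulate && !is.null(config[["input"]])) {
    for (side in c("training", "evaluation")) {
      s <- config[["input"]][[side]]
      if (is.null(s)) { v <- c(v, paste("input.", side, " is required")); next }
      bad <- setdiff(names(s), pipeline_schema$cohort)
      if (length(bad)) v <- c(v, paste0("unknown key(s) in input.", side, ": ",
                                        paste(bad, collapse = ", ")))
      if (is.null(s$genotypes)) v <- c(v, paste0("input.", side,
                                                 ".genotypes is required"))
      if (is.null(s$phenotypes)) v <- c(v, paste0("input.", side,
                                                  ".phenotypes is required"))
    }
    if (is.null(config[["input"]]$manifest)) v <- c(v, "input.manifest is required")
    same <- !is.null(config[["input"]]$training$genotypes) &&
      identical(config[["input"]]$training$genotypes,
                config[["input"]]$evaluation$genotypes)
    if (same && !isTRUE(config$allow_single_cohort)) {
      v <- c(v, paste("training and evaluation cohorts are identical;",
                      "set allow_single_cohort: true to override"))
    }
  }
  if (length(v)) v else TRUE
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

load_cohort <- function(spec, manifest) {
  gm <- read_genotypes(spec$genotypes, manifest,
                       dialect = spec$dialect %||% "tsv")
  phen <- read_phenotypes(spec$phenotypes,
                          status_dialect = spec$status_dialect %||%
                            "case_control")
  join_cohort(gm, phen)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full two-cohort PRS pipeline
#'
#' Executes, in order: cohort acquisition (simulation or file input), sample
#' call-rate filtering, SNP QC on the training cohort, per-SNP association
#' under both adjustment modes, LD estimation, construction of the six PRS
#' models (model1/model2/model3 crossed with unadjusted/age-adjusted
#' weights), scoring and evaluation (quartile ORs, trend OR, AUC) on the
#' evaluation cohort, and report/manifest output.
#'
#' @param config YAML path or named list; see [validate_config()].
#' @return Invisibly, a list with every intermediate (cohorts, QC, association
#'   tables, LD, models, evaluations) plus `out_dir` and `manifest`.
#' @export
run_pipeline <- function(config) {
  config_path <- if (is.character(config)) config else NULL
  if (is.character(config)) config <- yaml::read_yaml(config)
  ok <- validate_config(config)
  if (!isTRUE(ok)) stop("invalid config:\n  ", paste(ok, collapse = "\n  "))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  qc_cfg <- do.call(qc_config, config[["qc"]] %||% list())
  alpha <- config[["association"]]$alpha %||% 0.05
  r2_thr <- config[["ld"]]$r2_threshold %||% 0.5
  missing_policy <- config[["prs"]]$missing_policy %||% "impute_control_freq"
  cutpoint_source <- config[["prs"]]$cutpoint_source %||% "controls"

  counts <- list()
  if (isTRUE(config[["simulate"]])) {
    study <- stage("simulate", {
      sim_args <- config[["sim"]] %||% list()
      sim_args$seed <- config$seed
      study <- do.call(sim_config, sim_args)
      simulate_study(study)
    })
    manifest <- study$manifest
    train <- list(gm = study$cohort1$gm, phen = study$cohort1$phen,
                  log = list())
    eval_ <- list(gm = study$cohort2$gm, phen = study$cohort2$phen,
                  log = list())
    write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
    write_tsv(study$truth$snps, file.path(out_dir, "truth_snps.tsv"))
  } else {
    manifest <- stage("input", read_manifest(config[["input"]]$manifest))
    train <- stage("input", load_cohort(config[["input"]]$training, manifest))
    eval_ <- stage("input", load_cohort(config[["input"]]$evaluation, manifest))
    if (!isTRUE(config$allow_single_cohort) &&
        length(intersect(train$gm$sample_ids, eval_$gm$sample_ids))) {
      stop("training and evaluation cohorts share samples; ",
           "set allow_single_cohort: true to override")
    }
  }
  counts$train_in <- dim(train$gm)
  counts$eval_in <- dim(eval_$gm)

  # sample call-rate filter, both cohorts
  filt <- stage("sample_qc", {
    ft <- filter_samples_by_call_rate(train$gm, qc_cfg$call_rate_threshold)
    fe <- filter_samples_by_call_rate(eval_$gm, qc_cfg$call_rate_threshold)
    list(train = ft, eval_ = fe)
  })
  train_j <- join_cohort(filt$train$gm, train$phen)
  eval_j <- join_cohort(filt$eval_$gm, eval_$phen)
  write_tsv(data.frame(cohort = c(rep("training",
                                      length(filt$train$call_rates)),
                                  rep("evaluation",
                                      length(filt$eval_$call_rates))),
                       sample_id = c(names(filt$train$call_rates),
                                     names(filt$eval_$call_rates)),
                       call_rate = c(filt$train$call_rates,
                                     filt$eval_$call_rates),
                       excluded = c(names(filt$train$call_rates) %in%
                                      filt$train$excluded,
                                    names(filt$eval_$call_rates) %in%
                                      filt$eval_$excluded)),
            file.path(out_dir, "sample_qc.tsv"))

  # SNP QC on the training cohort; evaluation restricted to passing SNPs
  snp_qc <- stage("snp_qc",
                  apply_snp_filters(train_j$gm, train_j$phen, qc_cfg))
  write_tsv(snp_qc$results, file.path(out_dir, "snp_qc.tsv"))
  gm_train <- snp_qc$gm
  gm_eval <- subset_genotypes(eval_j$gm, snps = gm_train$snps$snp_id)
  counts$snps_pass <- ncol(gm_train$dosage)

  # association, both modes, on the training cohort
  assoc_u <- stage("association",
                   run_association(gm_train, train_j$phen, adjust_age = FALSE))
  assoc_a <- stage("association",
                   run_association(gm_train, train_j$phen, adjust_age = TRUE))
  assoc_u$p_bonferroni <- pmin(1, assoc_u$p * nrow(assoc_u))
  assoc_a$p_bonferroni <- pmin(1, assoc_a$p * nrow(assoc_a))
  write_tsv(assoc_u, file.path(out_dir, "assoc_unadjusted.tsv"))
  write_tsv(assoc_a, file.path(out_dir, "assoc_age_adjusted.tsv"))

  ld <- stage("ld", ld_matrix(gm_train))
  write_tsv(cbind(data.frame(snp_id = ld$snp_ids), as.data.frame(ld$r2)),
            file.path(out_dir, "ld_matrix.tsv"))

  ctrl_eaf <- {
    ctrl <- train_j$phen$status == "control"
    gm_ctrl <- subset_genotypes(gm_train, samples = which(ctrl))
    af <- allele_frequencies(gm_ctrl)
    stats::setNames(af$eaf, af$snp_id)
  }

  models <- list()
  evals <- list()
  rows <- list()
  for (ws in c("unadjusted", "age_adjusted")) {
    for (rule in c("model1", "model2", "model3")) {
      key <- paste(rule, ws, sep = ".")
      m <- stage(paste0("build_", key),
                 build_prs_model(assoc_u, assoc_a, ld, manifest, rule = rule,
                                 weight_source = ws, alpha = alpha,
                                 ld_threshold = r2_thr,
                                 control_eaf = ctrl_eaf))
      models[[key]] <- m
      ev <- stage(paste0("evaluate_", key),
                  evaluate_prs(gm_eval, eval_j$phen, m,
                               missing_policy = missing_policy,
                               cutpoint_source = cutpoint_source))
      evals[[key]] <- ev
      tab <- ev$quartiles$table
      rows[[key]] <- rbind(
        data.frame(model = rule, weight_source = ws, n_snps = ev$n_snps,
                   row = paste0("q", tab$quartile),
                   n_controls = tab$n_controls, n_cases = tab$n_cases,
                   or_ = tab$or_, ci_low = tab$ci_low,
                   ci_high = tab$ci_high, p = tab$p),
        data.frame(model = rule, weight_source = ws, n_snps = ev$n_snps,
                   row = "trend", n_controls = ev$auc$n_controls,
                   n_cases = ev$auc$n_cases, or_ = ev$trend$or_,
                   ci_low = ev$trend$ci_low, ci_high = ev$trend$ci_high,
                   p = ev$trend$p),
        data.frame(model = rule, weight_source = ws, n_snps = ev$n_snps,
                   row = "auc", n_controls = ev$auc$n_controls,
                   n_cases = ev$auc$n_cases, or_ = ev$auc$auc,
                   ci_low = ev$auc$ci_low, ci_high = ev$auc$ci_high,
                   p = NA_real_)
      )
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  write_tsv(report, file.path(out_dir, "evaluation.tsv"))

  scores <- do.call(rbind, lapply(names(evals), function(k) {
    data.frame(sample_id = names(evals[[k]]$scores),
               model = evals[[k]]$model_name,
               weight_source = evals[[k]]$weight_source,
               prs = unname(evals[[k]]$scores))
  }))
  write_tsv(scores, file.path(out_dir, "scores.tsv"))

  settings <- list(qc = unclass(qc_cfg), alpha = alpha,
                   ld_r2_threshold = r2_thr, missing_policy = missing_policy,
                   cutpoint_source = cutpoint_source)
  manifest_out <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    settings = settings,
    counts = list(
      training_samples_in = counts$train_in[1],
      training_samples_kept = length(train_j$gm$sample_ids),
      evaluation_samples_in = counts$eval_in[1],
      evaluation_samples_kept = length(eval_j$gm$sample_ids),
      snps_in = counts$train_in[2],
      snps_pass_qc = counts$snps_pass,
      models = lapply(models, function(m) length(m$snp_ids))
    )
  )
  jsonlite::write_json(manifest_out, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(
    c(list(settings = settings),
      list(report = report)),
    file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)

  invisible(list(out_dir = out_dir, manifest = manifest_out,
                 training = train_j, evaluation = eval_j,
                 snp_qc = snp_qc$results, assoc_unadjusted = assoc_u,
                 assoc_age_adjusted = assoc_a, ld = ld, models = models,
                 evaluations = evals, report = report))
}

# Hash of the analytic configuration; out_dir is excluded so the same
# analysis written to two places carries the same identity.
config_hash <- function(config) {
  config$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
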