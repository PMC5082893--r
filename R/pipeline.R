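#' Default end-to-end run configuration
#'
#' Desk-scale defaults mirroring the three-study design: a discovery
#' placebo cohort (n = 17), a validation cohort (20 placebo + 19 drug), and
#' a no-treatment observational cohort (n = 20). All tunables are echoed in
#' the run manifest.
#'
#' @param seed master seed (required for a valid run).
#' @return A `run_config` list. The `spec_args` element passes extra
#'   arguments (e.g. planted-model coefficients for a non-default grid)
#'   through to [cohort_spec()].
#' @export
default_run_config <- function(seed = NULL) {
  structure(list(
    seed = seed,
    dim = c(12L, 12L, 12L),
    n_volumes = 300L,
    n_discovery = 17L,
    n_validation_placebo = 20L,
    n_validation_drug = 19L,
    n_no_treatment = 20L,
    densities = density_grid(),
    outcome_density = 0.10,
    tfce = tfce_params(),
    n_perm = 500L,
    alpha = 0.05,
    min_count = 8L,
    responder_threshold = 20,
    epsilon = 10,
    placebo_ceiling = 5,
    scale = "VAS",
    spec_args = list(),
    out_dir = NULL
  ), class = "run_config")
}

# mean ROI degree per subject from a nodes x densities x subjects array
roi_degree_by_subject <- function(degrees, roi, k, subjects = NULL) {
  if (is.null(subjects)) subjects <- seq_len(dim(degrees)[3])
  apply(degrees[roi, k, subjects, drop = FALSE], 3, mean)
}

# nodes x subjects matrix at one density
deg_slice <- function(degrees, k, subjects) {
  matrix(degrees[, k, subjects], nrow = dim(degrees)[1])
}

validate_config <- function(config) {
  if (is.null(config$seed)) stop("config validation: a seed is required")
  ref <- default_run_config(seed = 0L)
  for (nm in names(ref))
    if (!nm %in% names(config) || is.null(config[[nm]]))
      config[nm] <- list(ref[[nm]])   # keeps NULL-valued entries present
  if (config$min_count > length(config$densities))
    stop("config validation: min_count exceeds the density grid")
  if (config$alpha <= 0 || config$alpha >= 1)
    stop("config validation: alpha must be in (0, 1)")
  config
}

#' Run the full discovery-to-validation pipeline on synthetic cohorts
#'
#' Executes the whole analysis as one reproducible run: simulate the three
#' cohorts, compute degree sweeps, contrast discovery responders vs
#' nonresponders with permutation/TFCE inference and the cross-density
#' conjunction, fit the discovery linear model on the resulting ROI, carry
#' it to the validation placebo arm (prediction correlation + ROC), and
#' decompose the drug arm into predicted-placebo and drug components,
#' including the drug-region search. Identical configs yield identical
#' outputs.
#'
#' @param config a [default_run_config()] list (possibly modified); a seed
#'   is mandatory.
#' @param progress print stage progress.
#' @return A `run_report` list; see the elements `discovery`, `model`,
#'   `validation`, `decomposition`, `no_treatment` and `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(), progress = FALSE) {
  config <- validate_config(config)
  t_all <- proc.time()["elapsed"]
  stage <- function(msg) if (progress) message(sprintf("[%6.1fs] %s",
    proc.time()["elapsed"] - t_all, msg))
  with_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }

  stage("simulate: discovery cohort")
  spec_disc <- do.call(cohort_spec, c(list(
    dim = config$dim, n_volumes = config$n_volumes,
    arms = c(placebo = config$n_discovery),
    density = config$outcome_density, seed = config$seed), config$spec_args))
  disc <- with_stage("simulate", generate_cohort(spec_disc, config$densities))

  stage("simulate: validation cohort")
  spec_val <- do.call(cohort_spec, c(list(
    dim = config$dim, n_volumes = config$n_volumes,
    arms = c(placebo = config$n_validation_placebo,
             drug = config$n_validation_drug),
    density = config$outcome_density, seed = config$seed + 1L),
    config$spec_args))
  val <- with_stage("simulate", generate_cohort(spec_val, config$densities))

  no_trt <- NULL
  if (config$n_no_treatment >= 2) {
    stage("simulate: no-treatment cohort")
    spec_nt <- do.call(cohort_spec, c(list(
      dim = config$dim, n_volumes = config$n_volumes,
      arms = c(`no-treatment` = config$n_no_treatment),
      density = config$outcome_density, seed = config$seed + 2L),
      config$spec_args))
    no_trt <- with_stage("simulate", generate_cohort(spec_nt, config$densities))
  }

  stage("contrast: discovery responders vs nonresponders")
  d_out <- subject_outcomes(disc$behavior, config$responder_threshold)
  resp <- d_out$responder
  nbr <- node_neighbors(disc$nodes$coords, config$tfce$connectivity)
  contrasts <- with_stage("contrast", lapply(seq_along(config$densities), function(k)
    permutation_fwe(deg_slice(disc$degrees, k, seq_along(resp)),
                    ifelse(resp, "responder", "nonresponder"),
                    nbr, n_perm = config$n_perm, params = config$tfce,
                    seed = config$seed + 100L + k)))
  conj <- conjunction_mask(contrasts, config$alpha, config$min_count)
  k10 <- which.min(abs(config$densities - config$outcome_density))
  clus <- cluster_report(conj$mask, contrasts[[k10]]$t, nbr, mm = disc$nodes$mm)
  roi <- if (nrow(clus) > 0) {
    lab <- label_components_cpp(conj$mask, nbr$idx, nbr$ptr)
    which(lab == which.max(tabulate(lab[lab > 0])))
  } else integer(0)

  stage("predict: discovery fit and validation transfer")
  model <- model_w <- validation <- NULL
  if (length(roi) > 0) {
    x_disc <- roi_degree_by_subject(disc$degrees, roi, k10)
    model <- with_stage("predict",
      fit_discovery_model(x_disc, d_out$analgesia_vas, scale = "VAS"))
    model_w <- fit_discovery_model(x_disc, d_out$analgesia_womac, scale = "WOMAC")

    v_out <- subject_outcomes(val$behavior, config$responder_threshold)
    plc <- which(v_out$arm == "placebo")
    x_val <- roi_degree_by_subject(val$degrees, roi, k10, plc)
    pred <- predict_outcome(model, x_val)
    obs <- v_out$analgesia_vas[plc]
    pv_cor <- cor.test(pred, obs)
    roc_p <- roc_auc(x_val, v_out$responder[plc])
    drg <- which(v_out$arm == "drug")
    x_drg <- roi_degree_by_subject(val$degrees, roi, k10, drg)
    roc_d <- tryCatch(roc_auc(x_drg, v_out$responder[drg]), error = function(e) NULL)
    cmp <- fisher_exact_2x2(sum(v_out$responder[plc]), sum(!v_out$responder[plc]),
                            sum(v_out$responder[drg]), sum(!v_out$responder[drg]))
    validation <- list(
      predicted = pred, observed = obs,
      prediction_r = unname(pv_cor$estimate), prediction_p = pv_cor$p.value,
      roc_placebo = roc_p, roc_drug = roc_d,
      responders_placebo = classify_responders(v_out$analgesia_vas[plc],
                                               config$responder_threshold),
      responders_drug = classify_responders(v_out$analgesia_vas[drg],
                                            config$responder_threshold),
      responder_fisher_p = cmp$p)
  } else {
    v_out <- subject_outcomes(val$behavior, config$responder_threshold)
    drg <- which(v_out$arm == "drug")
  }

  stage("decompose: drug arm")
  decomp <- drug_search <- drug_validation <- categories <- NULL
  if (!is.null(model)) {
    x_drg <- roi_degree_by_subject(val$degrees, roi, k10, drg)
    decomp <- decompose(model, v_out$analgesia_vas[drg], x_drg,
                        ids = v_out$id[drg], epsilon = config$epsilon)
    categories <- categorize_arm(decomp)
    pure <- select_pure_drug_responders(decomp, config$responder_threshold,
                                        config$placebo_ceiling)
    other_resp <- setdiff(decomp$id[decomp$empirical >= config$responder_threshold],
                          pure$id)
    if (nrow(pure) >= 1 && length(other_resp) >= 1) {
      i_pure <- match(pure$id, v_out$id[drg])
      i_other <- match(other_resp, v_out$id[drg])
      drug_search <- with_stage("decompose", drug_region_search(
        deg_slice(val$degrees, k10, drg[i_pure]),
        deg_slice(val$degrees, k10, drg[i_other]), nbr))
      reg_deg <- roi_degree_by_subject(val$degrees, drug_search$region, k10, drg)
      delta_w <- v_out$analgesia_womac[drg] - predict_outcome(model_w, x_drg)
      drug_validation <- validate_drug_region(
        reg_deg, list(VAS = decomp$delta, WOMAC = delta_w))
    }
  }

  no_treatment <- NULL
  if (!is.null(no_trt)) {
    nt_out <- subject_outcomes(no_trt$behavior, config$responder_threshold)
    no_treatment <- list(
      responders = classify_responders(nt_out$analgesia_vas,
                                       config$responder_threshold),
      mean_analgesia = mean(nt_out$analgesia_vas, na.rm = TRUE))
  }

  manifest <- list(
    config = config[setdiff(names(config), "tfce")],
    tfce = unclass(config$tfce),
    seeds = list(discovery = spec_disc$seed, validation = spec_val$seed,
                 permutation_base = config$seed + 100L),
    n_nodes = nrow(disc$degrees),
    versions = list(placebonet = as.character(utils::packageVersion("placebonet")),
                    r = R.version.string))

  report <- list(
    discovery = list(cohort = disc, outcomes = d_out, contrasts = contrasts,
                     conjunction = conj, clusters = clus, roi = roi,
                     responders = classify_responders(d_out$analgesia_vas,
                                                      config$responder_threshold)),
    model = model, model_womac = model_w,
    validation = validation,
    decomposition = list(table = decomp, categories = categories,
                         drug_region = drug_search,
                         drug_region_validation = drug_validation),
    no_treatment = no_treatment,
    manifest = manifest)
  class(report) <- "run_report"

  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  stage("done")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  discovery: %d/%d responders; conjunction %d voxels in %d cluster(s)\n",
              x$discovery$responders$n_responders, x$discovery$responders$n,
              sum(x$discovery$conjunction$mask), nrow(x$discovery$clusters)))
  if (!is.null(x$model))
    cat(sprintf("  model: y = %.3g x %+.3g (R2 %.2f)\n", x$model$a, x$model$b, x$model$r2))
  if (!is.null(x$validation))
    cat(sprintf("  validation: prediction r = %.3f (p = %.3g), placebo AUC = %.3f\n",
                x$validation$prediction_r, x$validation$prediction_p,
                x$validation$roc_placebo$auc))
  if (!is.null(x$decomposition$categories))
    cat(sprintf("  drug arm: %s\n", paste(names(x$decomposition$categories),
                x$decomposition$categories, sep = "=", collapse = ", ")))
  invisible(x)
}

# write tables, maps and the manifest of a finished run
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$discovery$clusters,
                   file.path(dir, "discovery_clusters.csv"), row.names = FALSE)
  if (!is.null(report$decomposition$table))
    utils::write.csv(as.data.frame(report$decomposition$table),
                     file.path(dir, "decomposition.csv"), row.names = FALSE)
  if (!is.null(report$model))
    jsonlite::write_json(list(a = report$model$a, b = report$model$b,
                              scale = report$model$scale, n = report$model$n,
                              r2 = report$model$r2),
                         file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  disc <- report$discovery$cohort
  write_map_nifti(as.numeric(report$discovery$conjunction$mask),
                  disc$nodes, disc$spec$dim,
                  file.path(dir, "conjunction_mask.nii.gz"),
                  voxel_mm = disc$spec$voxel_mm)
  files <- list.files(dir, full.names = TRUE)
  manifest <- report$manifest
  manifest$checksums <- as.list(tools::md5sum(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
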