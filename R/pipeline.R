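#' Pipeline configuration
#'
#' Binds the per-stage settings of an end-to-end run. Every stochastic
#' stage carries its own seed, so a configuration fully determines the
#' outputs. Unknown keys are rejected.
#'
#' @param task A [task_config()].
#' @param synth A [synth_spec()] plus cohort settings (`n_subjects`,
#'   `group`).
#' @param model List with `sampler` ([sampler_config()]) and `priors`
#'   ([hb_priors()]).
#' @param preproc List of preprocessing settings: `target_fs`,
#'   band edges `low`/`high`, `saccade_threshold`.
#' @param deconv List of CV settings: `grid`, `n_splits`, `test_frac`.
#' @param stats List with `n_perm`, `n_boot`, `alpha`.
#' @param seeds Named list of integer seeds, one per stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(task = task_config(),
                            synth = list(spec = synth_spec(),
                                         n_subjects = 34,
                                         group = list(mu = c(0, 0, 0),
                                                      delta = c(1.2, 1.2, 1.2))),
                            model = list(sampler = sampler_config(),
                                         priors = hb_priors()),
                            preproc = list(target_fs = 20, low = 0.05,
                                           high = 4, saccade_threshold = 3.3),
                            deconv = list(grid = seq(0, 1, length.out = 21),
                                          n_splits = 20, test_frac = 0.2),
                            stats = list(n_perm = 1000, n_boot = 10000,
                                         alpha = 0.05),
                            seeds = list(simulate = 1L, fit = 2L,
                                         deconvolve = 3L, stats = 4L)) {
  known <- c("spec", "n_subjects", "group")
  if (length(bad <- setdiff(names(synth), known)))
    stop("unknown synth config keys: ", paste(bad, collapse = ", "))
  if (length(bad <- setdiff(names(model), c("sampler", "priors"))))
    stop("unknown model config keys: ", paste(bad, collapse = ", "))
  if (length(bad <- setdiff(names(seeds),
                            c("simulate", "fit", "deconvolve", "stats"))))
    stop("unknown seed keys: ", paste(bad, collapse = ", "))
  structure(list(task = task, synth = synth, model = model,
                 preproc = preproc, deconv = deconv, stats = stats,
                 seeds = seeds),
            class = "pipeline_config")
}

.need <- function(path, stage, what) {
  if (!file.exists(path))
    stop("stage '", stage, "' needs ", what, " at ", path,
         "; run the producing stage first", call. = FALSE)
  path
}

## preprocess one raw recording given its annotations and trials
.preprocess_one <- function(ts, ann, pp) {
  ts <- interpolate_blinks(ts, ann$blinks)
  extra <- detect_residual_blinks(ts)
  if (nrow(extra) > 0) ts <- interpolate_blinks(ts, extra)
  ts <- pupil_bandpass(ts, low = pp$low %||% 0.05, high = pp$high %||% 4)
  ts <- zscore_resample(ts, target_fs = pp$target_fs %||% 20)
  remove_nuisance(ts, blink_times = ann$blinks$end,
                  saccade_times = ann$saccades$time)
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in order, reading and writing all
#' intermediate artifacts under `out_dir`:
#' \describe{
#'   \item{simulate}{generate and write the synthetic cohort
#'     (`data/`).}
#'   \item{fit}{hierarchical Bayesian fit of the Q-learning model to
#'     the learning-phase choices (`fit/`).}
#'   \item{preprocess}{blink interpolation, band-pass, per-run
#'     z-scoring, resampling, nuisance removal, trial rejection
#'     (`preproc/`).}
#'   \item{deconvolve}{per-subject ridge deconvolution of both phases
#'     with single-trial covariates from the fitted parameters
#'     (`deconv/`).}
#'   \item{stats}{group-level cluster permutation tests on the
#'     covariate responses and the across-subject bootstrap GLM
#'     (`stats/`).}
#' }
#'
#' @param config A [pipeline_config()].
#' @param stages Character subset of
#'   `c("simulate", "fit", "preprocess", "deconvolve", "stats")`.
#' @param out_dir Run directory.
#' @return Invisibly, a list of in-memory stage outputs (`cohort`,
#'   `fitsum`, `deconv`, `stats` as applicable).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "fit", "preprocess",
                                    "deconvolve", "stats"),
                         out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(out_dir, "data")
  out <- list()

  if ("simulate" %in% stages) {
    cohort <- generate_cohort(n_subjects = config$synth$n_subjects,
                              group = config$synth$group,
                              config = config$task, spec = config$synth$spec,
                              seed = config$seeds$simulate,
                              out_dir = data_dir)
    out$cohort <- cohort
  }
  subj_dirs <- sort(list.dirs(data_dir, recursive = FALSE))
  if (length(subj_dirs) == 0 && length(setdiff(stages, "simulate")))
    .need(file.path(data_dir, "sub-01"), stages[1], "simulated subject data")

  if ("fit" %in% stages) {
    data <- lapply(subj_dirs, function(d) {
      tr <- read_trials(.need(file.path(d, "trials.tsv"), "fit", "a trial table"))
      tr[tr$phase == "learning", ]
    })
    fit <- fit_hierarchical(data, sampler = config$model$sampler,
                            priors = config$model$priors)
    fitsum <- fit_summary(fit, data)
    fit_dir <- file.path(out_dir, "fit")
    dir.create(fit_dir, showWarnings = FALSE)
    write_draws(fit, file.path(fit_dir, "draws.tsv"))
    .write_tsv(fitsum, file.path(fit_dir, "fit_summary.tsv"))
    jsonlite::write_json(list(rhat = as.list(fit$rhat),
                              converged = fit$converged),
                         file.path(fit_dir, "diagnostics.json"),
                         auto_unbox = TRUE, digits = NA)
    out$fitsum <- fitsum
    out$fit <- fit
  }

  if ("preprocess" %in% stages) {
    pre_dir <- file.path(out_dir, "preproc")
    dir.create(pre_dir, showWarnings = FALSE)
    for (d in subj_dirs) {
      sub <- basename(d)
      trials <- read_trials(.need(file.path(d, "trials.tsv"), "preprocess",
                                  "a trial table"))
      for (phase in intersect(c("learning", "transfer"), unique(trials$phase))) {
        raw_path <- file.path(d, paste0(phase, "_pupil.tsv"))
        if (!file.exists(raw_path)) next
        ts <- read_pupil(raw_path)
        ann <- read_annotations(.need(file.path(d, paste0(phase, "_annotations.tsv")),
                                      "preprocess", "annotations"))
        clean <- .preprocess_one(ts, ann, config$preproc)
        write_pupil(clean, file.path(pre_dir, paste0(sub, "_", phase, "_clean.tsv")))
        keep <- reject_trials(trials[trials$phase == phase, ], ann$saccades,
                              threshold = config$preproc$saccade_threshold %||% 3.3,
                              rt_floor = config$task$rt_floor,
                              rt_deadline = config$task$rt_deadline)
        write_trials(keep$kept, file.path(pre_dir, paste0(sub, "_", phase, "_kept.tsv")))
      }
    }
  }

  if ("deconvolve" %in% stages) {
    pre_dir <- file.path(out_dir, "preproc")
    fit_path <- .need(file.path(out_dir, "fit", "fit_summary.tsv"),
                      "deconvolve", "the fit summary")
    fitsum <- .read_tsv(fit_path)
    dec_dir <- file.path(out_dir, "deconv")
    dir.create(dec_dir, showWarnings = FALSE)
    cvset <- list(grid = config$deconv$grid %||% seq(0, 1, length.out = 21),
                  n_splits = config$deconv$n_splits %||% 20,
                  test_frac = config$deconv$test_frac %||% 0.2,
                  seed = config$seeds$deconvolve)
    for (si in seq_along(subj_dirs)) {
      sub <- basename(subj_dirs[si])
      params <- agent_params(fitsum$alpha_gain[si], fitsum$alpha_loss[si],
                             fitsum$beta[si])
      all_learning <- read_trials(file.path(subj_dirs[si], "trials.tsv"))
      all_learning <- all_learning[all_learning$phase == "learning", ]
      traj_all <- compute_trajectory(all_learning, params)
      for (phase in c("learning", "transfer")) {
        clean_path <- file.path(pre_dir, paste0(sub, "_", phase, "_clean.tsv"))
        kept_path <- file.path(pre_dir, paste0(sub, "_", phase, "_kept.tsv"))
        if (!file.exists(clean_path)) {
          if (phase == "learning")
            .need(clean_path, "deconvolve", "preprocessed pupil data")
          next
        }
        ts <- read_pupil(clean_path)
        kept <- read_trials(kept_path)
        if (phase == "learning") {
          traj <- traj_all[match(kept$trial, all_learning$trial), ]
          specs <- learning_regressors(kept, traj)
        } else {
          vals <- transfer_values(attr(traj_all, "final_q"), kept)
          specs <- transfer_regressors(kept, vals, config$task)
        }
        res <- deconvolve(ts, specs, cv = cvset)
        write_betas(res, file.path(dec_dir, paste0(sub, "_", phase, "_betas.tsv")))
      }
    }
  }

  if ("stats" %in% stages) {
    dec_dir <- file.path(out_dir, "deconv")
    st_dir <- file.path(out_dir, "stats")
    dir.create(st_dir, showWarnings = FALSE)
    subs <- basename(subj_dirs)
    read_phase <- function(phase) {
      paths <- file.path(dec_dir, paste0(subs, "_", phase, "_betas.tsv"))
      if (!all(file.exists(paths)))
        .need(paths[!file.exists(paths)][1], "stats", "deconvolved betas")
      lapply(paths, read_betas)
    }
    betas_l <- read_phase("learning")
    betas_t <- tryCatch(read_phase("transfer"), error = function(e) NULL)
    stack <- function(betas, reg) {
      rows <- lapply(betas, function(b) b$beta[b$regressor == reg])
      lag <- betas[[1]]$lag[betas[[1]]$regressor == reg]
      list(mat = do.call(rbind, rows), lag = lag)
    }
    tests <- list()
    targets <- list(c("learning", "q_chosen_choice"),
                    c("learning", "q_unchosen_choice"),
                    c("learning", "rpe_fb"))
    if (!is.null(betas_t))
      targets <- c(targets, list(c("transfer", "q_chosen_choice")))
    for (tg in targets) {
      b <- if (tg[1] == "learning") betas_l else betas_t
      s <- stack(b, tg[2])
      ct <- cluster_permutation_test(s$mat, n_perm = config$stats$n_perm %||% 1000,
                                     alpha = config$stats$alpha %||% 0.05,
                                     seed = config$seeds$stats, times = s$lag)
      nm <- paste0(tg[1], "_", tg[2])
      tests[[nm]] <- ct
      write_clusters(ct, file.path(st_dir, paste0("clusters_", nm, ".tsv")))
    }
    # across-subject GLM: choice dilation and feedback amplitude vs
    # fitted parameters
    fitsum <- .read_tsv(.need(file.path(out_dir, "fit", "fit_summary.tsv"),
                              "stats", "the fit summary"))
    ch <- stack(betas_l, "choice")
    resp_choice <- interval_summary(ch$mat, ch$lag, c(-0.5, 0.5))
    fb <- stack(betas_l, "feedback")
    resp_fb <- apply(fb$mat, 1, feedback_amplitude, times = fb$lag)
    preds <- fitsum[, c("alpha_gain", "alpha_loss", "beta")]
    glms <- list(
      choice = bootstrap_glm(resp_choice, preds,
                             n_boot = config$stats$n_boot %||% 10000,
                             seed = config$seeds$stats),
      feedback_amplitude = bootstrap_glm(resp_fb, preds,
                                         n_boot = config$stats$n_boot %||% 10000,
                                         seed = config$seeds$stats + 1L))
    for (nm in names(glms))
      .write_tsv(glms[[nm]]$coef, file.path(st_dir, paste0("glm_", nm, ".tsv")))
    out$stats <- list(clusters = tests, glms = glms)
  }
  jsonlite::write_json(list(stages = stages, seeds = config$seeds,
                            timestamp = NULL),
                       file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
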