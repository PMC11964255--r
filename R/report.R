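#' Specification of one paired experimental group
#'
#' Bundles the control and irradiated phantom settings for one dose-level
#' and hydration combination (labels follow the DD/DT/DS/WD/WT/WS
#' convention: D/W = dry/wet, D/T/S = diagnostic/therapeutic/
#' sterilization).
#'
#' @param id group label, e.g. `"WS"`.
#' @param control_image,irradiated_image [phantom_image_config()] objects
#'   (seeds are reassigned by the pipeline).
#' @param control_E_GPa,irradiated_E_GPa ground-truth moduli for the
#'   indentation phantoms.
#' @param control_tau,irradiated_tau 2-element lists with `amplitudes`
#'   and `lifetimes_ns` for the decay phantoms.
#' @param control_ftir_state,irradiated_ftir_state `"native"` or
#'   `"denatured"`.
#' @return An `experiment_group` list.
#' @export
experiment_group <- function(id, control_image, irradiated_image,
                             control_E_GPa = 4.8, irradiated_E_GPa = 4.8,
                             control_tau = list(amplitudes = c(0.5, 0.3, 0.2),
                                                lifetimes_ns = c(0.8, 3.5, 12)),
                             irradiated_tau = control_tau,
                             control_ftir_state = "native",
                             irradiated_ftir_state = "native") {
  stopifnot(inherits(control_image, "phantom_image_config"),
            inherits(irradiated_image, "phantom_image_config"))
  structure(
    list(id = id, control_image = control_image,
         irradiated_image = irradiated_image,
         control_E_GPa = control_E_GPa, irradiated_E_GPa = irradiated_E_GPa,
         control_tau = control_tau, irradiated_tau = irradiated_tau,
         control_ftir_state = control_ftir_state,
         irradiated_ftir_state = irradiated_ftir_state),
    class = "experiment_group"
  )
}

#' Experiment configuration for the end-to-end pipeline
#'
#' @param groups list of [experiment_group()]s with unique ids.
#' @param seed master integer seed; all stage seeds derive from it.
#' @param n_images phantom images per sample member (default 2).
#' @param n_curves force curves per member (default 40).
#' @param n_decays decay histograms per member (default 3).
#' @param n_spectra FTIR spectra per member (default 3).
#' @param decay_photons photons per decay histogram (default 2e5; the
#'   acquisition protocol's 1e6 peak target scales linearly and is used in
#'   the acceptance checks).
#' @param training_field_um field size of the classifier-training phantoms
#'   (default 10; smaller fields give faster, smaller training sets).
#' @param output_dir optional directory for TSV tables and the manifest.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(groups, seed = 1L, n_images = 2L,
                              n_curves = 40L, n_decays = 3L, n_spectra = 3L,
                              decay_photons = 2e5, training_field_um = 10,
                              output_dir = NULL) {
  stopifnot(is.list(groups), length(groups) >= 1,
            all(vapply(groups, inherits, logical(1), "experiment_group")))
  ids <- vapply(groups, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stopf("group ids must be unique")
  names(groups) <- ids
  structure(
    list(groups = groups, seed = as.integer(seed),
         n_images = as.integer(n_images), n_curves = as.integer(n_curves),
         n_decays = as.integer(n_decays), n_spectra = as.integer(n_spectra),
         decay_photons = decay_photons,
         training_field_um = training_field_um, output_dir = output_dir),
    class = "experiment_config"
  )
}

#' Default six-group experiment emulation
#'
#' The stated world of the emulated experiment: six paired groups
#' (DD/DT/DS/WD/WT/WS). Morphometry: every irradiated member shares its
#' control's phantom settings except WS, whose irradiated phantoms lose
#' banding, gain blur and gain kinks (the degradation pattern the wet
#' sterilization group shows). Mechanics: control moduli at the observed
#' control medians with the reported percent variations applied to the
#' irradiated members. Lifetimes: sterilization groups change by +6%
#' (dry) and -5% (wet); others are null. FTIR: all native.
#'
#' @param seed master seed.
#' @param ... passed to [experiment_config()] (e.g. `n_images`,
#'   `output_dir`).
#' @return An `experiment_config`.
#' @export
default_experiment_config <- function(seed = 1L, ...) {
  base_img <- function(s) phantom_image_config(seed = s)
  # partial degradation just beyond the label cutoffs: scans remain
  # analyzable, as the degraded wet-sterilization samples were
  degraded_img <- function(s) {
    phantom_image_config(dband_depth = 0, blur_sigma_nm = 32,
                         kink_prob = 0.8, noise_sigma_nm = 2.5, seed = s)
  }
  tau_base <- list(amplitudes = c(0.5, 0.3, 0.2), lifetimes_ns = c(0.8, 3.5, 12))
  scale_tau <- function(f) list(amplitudes = tau_base$amplitudes,
                                lifetimes_ns = tau_base$lifetimes_ns * f)
  ctrl_E <- c(DD = 4.82, DT = 4.83, DS = 5.43, WD = 3.94, WT = 4.65, WS = 5.27)
  var_pct <- c(DD = +2.1, DT = -8.3, DS = -26.4, WD = +7.7, WT = +6.5, WS = +55.8)
  lt_factor <- c(DD = 1, DT = 1, DS = 1.06, WD = 1, WT = 1, WS = 0.95)
  groups <- lapply(names(ctrl_E), function(g) {
    irr_img <- if (g == "WS") degraded_img(0L) else base_img(0L)
    experiment_group(
      id = g,
      control_image = base_img(0L), irradiated_image = irr_img,
      control_E_GPa = ctrl_E[[g]],
      irradiated_E_GPa = ctrl_E[[g]] * (1 + var_pct[[g]] / 100),
      control_tau = tau_base, irradiated_tau = scale_tau(lt_factor[[g]])
    )
  })
  experiment_config(groups, seed = seed, ...)
}

# reseed a phantom image config (derive per-sample seeds from the master)
reseed <- function(cfg, seed) { cfg$seed <- as.integer(seed %% 2^30); cfg }

# classifier training set: paired phantoms placing both classes of each
# metric on either side of the label cutoffs
make_training_set <- function(seed, field_um = 10) {
  cfgs <- list(
    banded    = phantom_image_config(field_um, dband_depth = 0.35,
                                     seed = seed + 11L),
    unbanded  = phantom_image_config(field_um, dband_depth = 0,
                                     seed = seed + 12L),
    clear     = phantom_image_config(field_um, seed = seed + 13L),
    blurry    = phantom_image_config(field_um, blur_sigma_nm = 45,
                                     noise_sigma_nm = 3, seed = seed + 14L),
    random    = phantom_image_config(field_um, orientation_mode = "random",
                                     seed = seed + 15L),
    aligned   = phantom_image_config(field_um, orientation_mode = "aligned",
                                     aligned_axis_deg = 30, seed = seed + 16L),
    kinked    = phantom_image_config(field_um, kink_prob = 1, n_fibrils = 18,
                                     seed = seed + 17L),
    straight  = phantom_image_config(field_um, kink_prob = 0,
                                     seed = seed + 18L),
    # degraded-condition examples: the training set must span every
    # experimental group, including degraded scans, or the classifiers
    # drift under the blur/noise covariate shift of degraded samples
    kinked_degraded  = phantom_image_config(field_um, kink_prob = 1,
                                            n_fibrils = 18, dband_depth = 0,
                                            blur_sigma_nm = 32,
                                            noise_sigma_nm = 2.5,
                                            seed = seed + 19L),
    aligned_degraded = phantom_image_config(field_um,
                                            orientation_mode = "aligned",
                                            aligned_axis_deg = 120,
                                            dband_depth = 0,
                                            blur_sigma_nm = 32,
                                            noise_sigma_nm = 2.5,
                                            seed = seed + 20L)
  )
  feats <- list(); labs <- list()
  for (nm in names(cfgs)) {
    gen <- generate_fibril_image(cfgs[[nm]])
    rois <- patch_image(gen$image)
    feats[[nm]] <- feature_matrix(lapply(rois, extract_features))
    labs[[nm]] <- gen$labels
  }
  X <- do.call(rbind, feats)
  lab <- do.call(rbind, labs)
  list(features = X, labels = lab)
}

texture_metrics <- c("dbanding", "clarity", "random_orientation", "linearity")

#' Run the end-to-end experiment emulation
#'
#' Generates phantoms for every group, trains the four texture
#' classifiers on a dedicated labelled phantom training set, and emits
#' the report bundle: classifier consistency (with thresholds),
#' per-sample prevalences, control-vs-irradiated change tables with
#' exceedance flags, per-group modulus summaries with rank tests,
#' per-condition lifetime summaries, and FTIR band metrics, plus a run
#' manifest with every seed. Stages fail independently: a failed stage is
#' recorded in `$failed` and the rest proceed.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-stage progress.
#' @return list with `table1_consistency`, `table2_change`,
#'   `table3_prevalence`, `table4_moduli`, `fig5_lifetimes`,
#'   `ftir_metrics`, `manifest`, `failed`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- Sys.time()
  seed <- config$seed
  out <- list(failed = character(0))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      warning(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
              call. = FALSE)
      out$failed <<- c(out$failed, name)
      NULL
    })
  }

  # --- texture: training + consistency -------------------------------
  say("training texture classifiers")
  classifiers <- NULL
  thresholds <- NULL
  train <- stage("texture-train",
                 make_training_set(seed, config$training_field_um))
  if (!is.null(train)) {
    classifiers <- lapply(texture_metrics, function(mt) {
      train_metric_classifier(train$features, train$labels[[mt]], metric = mt,
                              prior = "balanced")
    })
    names(classifiers) <- texture_metrics
    out$table1_consistency <- stage("texture-loo", {
      do.call(rbind, lapply(texture_metrics, function(mt) {
        rep <- loo_consistency(train$features, train$labels[[mt]], metric = mt,
                               prior = "balanced")
        data.frame(metric = mt, consistency_pct = rep$consistency_pct,
                   threshold_pct = rep$threshold_pct, n_rois = rep$n_rois,
                   stringsAsFactors = FALSE)
      }))
    })
    if (!is.null(out$table1_consistency)) {
      thresholds <- stats::setNames(out$table1_consistency$threshold_pct,
                                    out$table1_consistency$metric)
    }
  }

  # --- texture: prevalence + change per group ------------------------
  prev_rows <- list(); chg_rows <- list()
  if (!is.null(classifiers)) {
    for (g in config$groups) {
      say("texture group %s", g$id)
      res <- stage(paste0("texture-", g$id), {
        member_prev <- function(img_cfg, member, off) {
          Xs <- lapply(seq_len(config$n_images), function(k) {
            cfg <- reseed(img_cfg, seed + off + 97L * k)
            rois <- patch_image(generate_fibril_image(cfg)$image)
            feature_matrix(lapply(rois, extract_features))
          })
          X <- do.call(rbind, Xs)
          pt <- prevalence_table(classifiers, X)
          pt$group <- g$id; pt$member <- member
          pt
        }
        pc <- member_prev(g$control_image, "control", 1000L)
        # a paired null (irradiated config identical to control) emulates
        # re-imaging the same unchanged sample: reuse the seed stream so
        # the pair is exactly null
        irr_off <- if (identical(g$control_image, g$irradiated_image))
          1000L else 2000L
        pi_ <- member_prev(g$irradiated_image, "irradiated", irr_off)
        cp <- stats::setNames(pc$prevalence_pct, pc$metric)
        ip <- stats::setNames(pi_$prevalence_pct, pi_$metric)
        ct <- change_table(cp, ip, thresholds)
        ct$group <- g$id
        list(prev = rbind(pc, pi_), chg = ct)
      })
      if (!is.null(res)) {
        prev_rows[[g$id]] <- res$prev
        chg_rows[[g$id]] <- res$chg
      }
    }
    out$table3_prevalence <- if (length(prev_rows)) do.call(rbind, c(prev_rows, make.row.names = FALSE))
    out$table2_change <- if (length(chg_rows)) do.call(rbind, c(chg_rows, make.row.names = FALSE))
  }

  # --- mechanics ------------------------------------------------------
  say("mechanics")
  out$table4_moduli <- stage("mechanics", {
    rows <- list()
    for (g in config$groups) {
      fits_of <- function(E, off) {
        lapply(seq_len(config$n_curves), function(k) {
          fc <- generate_force_curve(force_curve_config(
            E, force_noise_nN = 0.5,
            seed = (seed + off + 31L * k) %% 2^30))
          fit_hertz_pyramid(fc)
        })
      }
      ctrl <- summarize_group(fits_of(g$control_E_GPa, 3000L),
                              group_id = paste0("C", g$id))
      irr <- summarize_group(fits_of(g$irradiated_E_GPa, 4000L),
                             paired_control = ctrl,
                             group_id = paste0("R", g$id))
      rows[[g$id]] <- data.frame(
        group = g$id,
        member = c("control", "irradiated"),
        n = c(ctrl$n, irr$n),
        median_GPa = c(ctrl$median_GPa, irr$median_GPa),
        variation_pct = c(NA, irr$variation_pct),
        p_value = c(NA, irr$p_value),
        significant = c(NA, irr$significant),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, c(rows, make.row.names = FALSE))
  })

  # --- FLIM -----------------------------------------------------------
  say("lifetimes")
  out$fig5_lifetimes <- stage("flim", {
    fits <- list(); pairing <- character(0)
    for (g in config$groups) {
      for (member in c("control", "irradiated")) {
        tau <- if (member == "control") g$control_tau else g$irradiated_tau
        off <- if (member == "control") 5000L else 6000L
        cond <- paste0(if (member == "control") "C" else "R", g$id)
        fits[[cond]] <- lapply(seq_len(config$n_decays), function(k) {
          h <- generate_decay_histogram(decay_config(
            tau$amplitudes, tau$lifetimes_ns,
            n_photons = config$decay_photons,
            seed = (seed + off + 7L * k) %% 2^30))
          fit_triexponential(h)
        })
        if (member == "irradiated") pairing[cond] <- paste0("C", g$id)
      }
    }
    summarize_lifetimes(fits, pairing)
  })

  # --- FTIR -----------------------------------------------------------
  say("ftir")
  out$ftir_metrics <- stage("ftir", {
    rows <- list()
    for (g in config$groups) {
      for (member in c("control", "irradiated")) {
        state <- if (member == "control") g$control_ftir_state
                 else g$irradiated_ftir_state
        off <- if (member == "control") 7000L else 8000L
        ms <- lapply(seq_len(config$n_spectra), function(k) {
          s <- generate_ftir_spectrum(spectrum_config(
            state, noise_sd = 0.005,
            seed = (seed + off + 13L * k) %% 2^30))
          band_metrics(preprocess_spectrum(s))
        })
        rows[[paste(g$id, member)]] <- data.frame(
          group = g$id, member = member, n = length(ms),
          amideI_peak_cm1 = mean(vapply(ms, `[[`, 1, "amideI_peak_cm1")),
          amideI_II_ratio = mean(vapply(ms, `[[`, 1, "amideI_II_ratio")),
          triplet_present_frac =
            mean(vapply(ms, `[[`, TRUE, "amideIII_triplet_present")),
          denatured_frac =
            mean(vapply(ms, `[[`, TRUE, "denatured_signature")),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(rows, make.row.names = FALSE))
  })

  out$manifest <- list(
    package_version = as.character(utils::packageVersion("collafib")),
    seed = seed,
    n_images = config$n_images, n_curves = config$n_curves,
    n_decays = config$n_decays, n_spectra = config$n_spectra,
    decay_photons = config$decay_photons,
    groups = names(config$groups),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    failed_stages = out$failed
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      if (!is.null(df)) {
        utils::write.table(df, file.path(config$output_dir,
                                         paste0(name, ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
    wr(out$table1_consistency, "table1_consistency")
    wr(out$table2_change, "table2_change")
    wr(out$table3_prevalence, "table3_prevalence")
    wr(out$table4_moduli, "table4_moduli")
    wr(out$fig5_lifetimes, "fig5_lifetimes")
    wr(out$ftir_metrics, "ftir_metrics")
    jsonlite::write_json(out$manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
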