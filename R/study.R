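#' Study configuration
#'
#' Collects every tunable of the end-to-end reproducibility pipeline in one
#' serialisable object. The defaults embody the emulated scanning and
#' modelling protocol: 0.6 mm voxels, five-rod calibration, 3 mm median
#' mask smoothing, 1 mm quadratic tetrahedra, the trabecular density-
#' elasticity and density-strength power laws, 1.9% apparent compressive
#' strain, 2 mm probes.
#'
#' @param n_control,n_lytic vertebra counts.
#' @param seed master seed.
#' @param phantom_args arguments for [make_vertebra_phantom()].
#' @param scanner_args arguments for [scanner_model()].
#' @param intra_args,inter_args arguments for [operator_profile()]
#'   overriding the presets.
#' @param elem_size_mm FE element size.
#' @param smooth_kernel_mm median-smoothing window.
#' @param apparent_strain imposed apparent strain.
#' @param n_increments displacement increments.
#' @param nu Poisson's ratio.
#' @param bc boundary-condition variant for [solve_compression()].
#' @param elastic run the solves with unbounded yield stress.
#' @param probe_radius_mm probe radius.
#' @param out_dir optional output directory for artefacts and reports.
#' @return a list of class `study_config`; round-trips through YAML via
#'   [write_study_config()] / [read_study_config()].
#' @export
study_config <- function(n_control = 3, n_lytic = 3, seed = 1,
                         phantom_args = list(), scanner_args = list(),
                         intra_args = list(), inter_args = list(),
                         elem_size_mm = 1, smooth_kernel_mm = 3,
                         apparent_strain = 0.019, n_increments = 10,
                         nu = 0.3, bc = "default", elastic = FALSE,
                         probe_radius_mm = 2, out_dir = NULL) {
  cfg <- list(n_control = n_control, n_lytic = n_lytic, seed = seed,
              phantom_args = phantom_args, scanner_args = scanner_args,
              intra_args = intra_args, inter_args = inter_args,
              elem_size_mm = elem_size_mm, smooth_kernel_mm = smooth_kernel_mm,
              apparent_strain = apparent_strain, n_increments = n_increments,
              nu = nu, bc = bc, elastic = elastic,
              probe_radius_mm = probe_radius_mm, out_dir = out_dir)
  class(cfg) <- "study_config"
  cfg
}

#' @rdname study_config
#' @param cfg a `study_config`.
#' @param path YAML file path.
#' @export
write_study_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname study_config
#' @export
read_study_config <- function(path) {
  do.call(study_config, yaml::read_yaml(path))
}

#' Run the end-to-end reproducibility study
#'
#' Synthesises the study set (phantoms, QCT scans, operator masks), then
#' for every vertebra: calibrates the scan from the rod ROIs, smooths the
#' masks, computes the intra- and inter-operator geometric agreement,
#' builds and solves an FE model per mask (memoised on identical masks),
#' and assembles the precision statistics (CV per vertebra, PE across
#' vertebrae, ARD per pair, paired tests and exploratory regressions when
#' enough vertebrae are available).
#'
#' @param cfg a [study_config()].
#' @param study optionally a pre-built [make_study()] set (the config's
#'   generator settings are then ignored).
#' @return a `repro_report`.
#' @export
run_study <- function(cfg = study_config(), study = NULL) {
  t0 <- Sys.time()
  if (is.null(study)) {
    presets <- list(
      intra = do.call(operator_profile,
                      modifyList(as.list(unclass(operator_preset("intra"))),
                                 cfg$intra_args)),
      inter = do.call(operator_profile,
                      modifyList(as.list(unclass(operator_preset("inter"))),
                                 cfg$inter_args)))
    study <- make_study(n_control = cfg$n_control, n_lytic = cfg$n_lytic,
                        presets = presets, seed = cfg$seed,
                        phantom_args = cfg$phantom_args,
                        scanner = do.call(scanner_model, cfg$scanner_args))
  }
  mech_names <- c("F_U", "sigma_U", "K", "E_APP")
  geo_names <- c("rvd", "dice", "msd_mm", "hd_mm")
  per_vertebra <- list()
  solve_cache <- new.env(parent = emptyenv())

  for (v in study$vertebrae) {
    sp <- v$phantom$spacing
    calib <- calibrate_from_rods(v$qct)
    smoothed <- lapply(v$masks, median_smooth_mask, spacing = sp,
                       kernel_mm = cfg$smooth_kernel_mm)
    geo <- list(
      intra = pairwise_geometric_summary(
        smoothed[c("op1_rep1", "op1_rep2", "op1_rep3")], sp,
        mode = "intra", smooth = FALSE),
      inter = pairwise_geometric_summary(
        smoothed[c("op1_rep1", "op2_rep1", "op3_rep1")], sp,
        mode = "inter", smooth = FALSE))

    run_one <- function(mask) {
      key <- mask_digest(mask)
      if (!is.null(solve_cache[[key]])) return(solve_cache[[key]])
      # one set of landmarks (the phantom's analytic ones) for every mask of
      # a vertebra: alignment is kept operator-independent, mirroring the
      # single-operator alignment protocol that minimises rotational
      # variability between models of the same vertebra
      model <- build_fe_model(mask, sp, bmd = calib$image,
                              elem_size = cfg$elem_size_mm,
                              landmarks = v$phantom$landmarks)
      result <- solve_compression(model,
                                  apparent_strain = cfg$apparent_strain,
                                  n_increments = cfg$n_increments,
                                  nu = cfg$nu, bc = cfg$bc,
                                  elastic = cfg$elastic)
      out <- list(model = model, summary = mechanical_summary(result, model))
      solve_cache[[key]] <- out
      out
    }
    mech <- lapply(smoothed, function(m) run_one(m)$summary)
    mech_tab <- do.call(rbind, mech)
    mech_tab$mask <- names(smoothed)
    cv_of <- function(masks, metric) {
      coefficient_of_variation(mech_tab[[metric]][match(masks, mech_tab$mask)])
    }
    intra_set <- c("op1_rep1", "op1_rep2", "op1_rep3")
    inter_set <- c("op1_rep1", "op2_rep1", "op3_rep1")
    cv <- list(
      intra = vapply(mech_names, cv_of, numeric(1), masks = intra_set),
      inter = vapply(mech_names, cv_of, numeric(1), masks = inter_set))
    ard_of <- function(masks, metric) {
      vals <- mech_tab[[metric]][match(masks, mech_tab$mask)]
      pairs <- list(c(1, 2), c(1, 3), c(2, 3))
      vapply(pairs, function(p) absolute_relative_difference(vals[p[1]], vals[p[2]]),
             numeric(1))
    }
    ard <- list(
      intra = vapply(mech_names, ard_of, numeric(3), masks = intra_set),
      inter = vapply(mech_names, ard_of, numeric(3), masks = inter_set))
    mean_of <- function(masks, metric) mean(mech_tab[[metric]][match(masks, mech_tab$mask)])
    means <- list(
      intra = vapply(mech_names, mean_of, numeric(1), masks = intra_set),
      inter = vapply(mech_names, mean_of, numeric(1), masks = inter_set))
    per_vertebra[[v$id]] <- list(id = v$id, condition = v$condition,
                                 calibration = calib$model, geometric = geo,
                                 mechanics = mech_tab, cv = cv, ard = ard,
                                 means = means)
  }

  report <- build_repro_report(per_vertebra, mech_names, geo_names)
  report$seed <- study$seed
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (!is.null(cfg$out_dir)) write_repro_report(report, cfg$out_dir)
  report
}

#' Assemble the reproducibility report
#'
#' Pools per-vertebra geometric and mechanical results into the study-level
#' tables: per-vertebra mean +/- SD of the geometric metrics (intra and
#' inter), per-vertebra CVs and the cross-vertebra precision error for
#' each mechanical metric, paired intra-vs-inter tests (n >= 3 vertebrae)
#' and exploratory SD(geometric) vs CV(mechanical) regressions.
#'
#' @param per_vertebra list of per-vertebra result bundles (see
#'   [run_study()]).
#' @param mech_names,geo_names metric names.
#' @return object of class `repro_report`.
#' @export
build_repro_report <- function(per_vertebra,
                               mech_names = c("F_U", "sigma_U", "K", "E_APP"),
                               geo_names = c("rvd", "dice", "msd_mm", "hd_mm")) {
  ids <- names(per_vertebra)
  n <- length(ids)
  geo_rows <- list()
  for (mode in c("intra", "inter")) {
    for (id in ids) {
      g <- per_vertebra[[id]]$geometric[[mode]]
      geo_rows[[paste(mode, id)]] <- data.frame(
        mode = mode, vertebra = id, metric = geo_names,
        mean = unname(g$mean[geo_names]), sd = unname(g$sd[geo_names]))
    }
    pooled <- do.call(rbind, lapply(ids, function(id) {
      g <- per_vertebra[[id]]$geometric[[mode]]
      g$mean[geo_names]
    }))
    geo_rows[[paste(mode, "pooled")]] <- data.frame(
      mode = mode, vertebra = "pooled", metric = geo_names,
      mean = colMeans(pooled),
      sd = if (n > 1) apply(pooled, 2, sd) else rep(0, length(geo_names)))
  }
  geometric_table <- do.call(rbind, geo_rows)
  rownames(geometric_table) <- NULL

  cv_table <- do.call(rbind, lapply(ids, function(id) {
    pv <- per_vertebra[[id]]
    data.frame(vertebra = id, condition = pv$condition,
               metric = rep(mech_names, 2),
               mode = rep(c("intra", "inter"), each = length(mech_names)),
               cv = c(unname(pv$cv$intra), unname(pv$cv$inter)))
  }))
  pe <- do.call(rbind, lapply(c("intra", "inter"), function(mode) {
    data.frame(mode = mode, metric = mech_names,
               pe = vapply(mech_names, function(m) {
                 precision_error(cv_table$cv[cv_table$mode == mode &
                                               cv_table$metric == m])
               }, numeric(1)))
  }))

  tests <- NULL
  regressions <- NULL
  if (n >= 3) {
    tests <- lapply(mech_names, function(m) {
      intra <- vapply(ids, function(id) per_vertebra[[id]]$means$intra[[m]], numeric(1))
      inter <- vapply(ids, function(id) per_vertebra[[id]]$means$inter[[m]], numeric(1))
      c(list(metric = m), paired_intra_inter_test(intra, inter))
    })
    regressions <- list()
    for (mode in c("intra", "inter")) {
      for (gm in geo_names) {
        sd_g <- vapply(ids, function(id) {
          per_vertebra[[id]]$geometric[[mode]]$sd[[gm]]
        }, numeric(1))
        for (mm in mech_names) {
          cv_m <- cv_table$cv[cv_table$mode == mode & cv_table$metric == mm]
          key <- sprintf("%s_sd_%s_vs_cv_%s", mode, gm, mm)
          regressions[[key]] <- tryCatch(
            c(list(mode = mode, geometric = gm, mechanical = mm),
              geometric_mechanical_regression(sd_g, cv_m)),
            error = function(e) NULL)
        }
      }
    }
    regressions <- Filter(Negate(is.null), regressions)
  }

  structure(list(geometric_table = geometric_table, cv_table = cv_table,
                 precision_error = pe, tests = tests,
                 regressions = regressions, per_vertebra = per_vertebra,
                 n_vertebrae = n),
            class = "repro_report")
}

#' Write a reproducibility report to disk (CSV + JSON)
#' @param report a `repro_report`.
#' @param out_dir output directory.
#' @export
write_repro_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$geometric_table, file.path(out_dir, "geometric_table.csv"),
            row.names = FALSE)
  write.csv(report$cv_table, file.path(out_dir, "mechanical_cv.csv"),
            row.names = FALSE)
  write.csv(report$precision_error, file.path(out_dir, "precision_error.csv"),
            row.names = FALSE)
  if (!is.null(report$regressions)) {
    reg <- do.call(rbind, lapply(report$regressions, function(r) {
      data.frame(mode = r$mode, geometric = r$geometric, mechanical = r$mechanical,
                 slope = r$slope, intercept = r$intercept,
                 r_squared = r$r_squared, p = r$p, n = r$n)
    }))
    write.csv(reg, file.path(out_dir, "regressions.csv"), row.names = FALSE)
  }
  keep <- report[c("precision_error", "tests", "n_vertebrae", "seed")]
  jsonlite::write_json(keep, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.repro_report <- function(x, ...) {
  cat(sprintf("Reproducibility report: %d vertebrae\n", x$n_vertebrae))
  cat("Precision error (RMS CV) per mechanical metric:\n")
  print(x$precision_error, row.names = FALSE)
  invisible(x)
}
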