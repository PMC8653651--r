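#' Split a labelled spectra set into calibration and test subsets
#'
#' Default rule: within every concentration level the samples are shuffled
#' (seeded, one substream per level) and then assigned alternately to the
#' calibration and test subsets, giving an even per-level split. Under the
#' default 210-sample design every one of the 21 levels (0, 5, ..., 95, 100 %
#' w/w) contributes 5 samples to each subset, i.e. 105 calibration and 105
#' test samples. Pure-adulterant (100 %) samples can instead be excluded from
#' both subsets via `pure_adulterant = "exclude"`.
#'
#' @param x A [spectra_set()] whose metadata carries fractions.
#' @param pure_adulterant `"split"` (default) or `"exclude"`.
#' @param seed Integer seed for the within-level shuffles.
#' @return List with `calibration`, `test` (both [spectra_set()]s with subset
#'   labels written in) and `excluded` (possibly 0-row tibble of ids).
#' @export
split_train_test <- function(x, pure_adulterant = c("split", "exclude"),
                             seed = 1L) {
  pure_adulterant <- match.arg(pure_adulterant)
  stopifnot(inherits(x, "spectra_set"))
  fr <- x$meta$fraction
  if (anyNA(fr)) rlang::abort("all samples must be labelled to split.")
  excluded_idx <- integer()
  assignable <- seq_len(n_samples(x))
  if (pure_adulterant == "exclude") {
    excluded_idx <- which(fr == 100)
    assignable <- setdiff(assignable, excluded_idx)
  }
  subset <- rep(NA_character_, n_samples(x))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  for (lev in sort(unique(fr[assignable]))) {
    idx <- assignable[fr[assignable] == lev]
    if (length(idx) < 2) {
      rlang::abort(sprintf(
        "level %g %% w/w has %d sample(s); the even split needs >= 2.",
        lev, length(idx)))
    }
    set.seed((as.integer(seed) + 7919L * as.integer(round(lev * 100))) %%
               2147483629L)
    idx <- idx[sample.int(length(idx))]
    subset[idx] <- rep(c("calibration", "test"), length.out = length(idx))
  }
  meta <- x$meta
  meta$subset <- ifelse(is.na(subset), "unassigned", subset)
  full <- spectra_set(x$wavenumber, x$absorbance, meta)
  list(
    calibration = filter_samples(full, subset == "calibration"),
    test = filter_samples(full, subset == "test"),
    excluded = meta[meta$subset == "unassigned", ]
  )
}

#' Screen pretreatment chains by cross-validated error
#'
#' Cross-validates a PLS model for every candidate chain on the given set
#' (each chain fitted on that same set — pass calibration samples only for
#' leakage-free screening, or the whole labelled set to mirror whole-set
#' screening) and tabulates RMSECV and R^2, sorted best-first.
#'
#' @param x A labelled [spectra_set()] of screening samples.
#' @param candidates Named list of [preprocessing_spec()]s (default: the nine
#'   [standard_chains()]).
#' @param scheme CV scheme (default 21-fold).
#' @param max_nlvs Largest latent-variable count scored.
#' @return Tibble with columns `method`, `nlvs`, `rmsecv`, `r2`, `winner`,
#'   sorted by RMSECV ascending.
#' @export
screen_preprocessing <- function(x, candidates = standard_chains(),
                                 scheme = cv_kfold(21), max_nlvs = 15) {
  stopifnot(inherits(x, "spectra_set"))
  if (length(candidates) == 0) rlang::abort("no candidate chains given.")
  if (is.null(names(candidates))) {
    names(candidates) <- purrr::map_chr(candidates, chain_name)
  }
  rows <- purrr::imap_dfr(candidates, function(spec, nm) {
    fitted <- fit_preprocessor(spec, x)
    m <- apply_preprocessor(fitted, x$absorbance)
    cv <- cross_validate(m, x$meta$fraction, max_nlvs = max_nlvs,
                         scheme = scheme)
    tibble::tibble(method = nm, nlvs = cv$chosen_nlvs,
                   rmsecv = cv$rmsecv, r2 = cv$r2)
  })
  rows <- rows[order(rows$rmsecv), ]
  rows$winner <- seq_len(nrow(rows)) == 1
  rows
}

#' Compare wavelength-selection methods on a calibration set
#'
#' Preprocesses the calibration set with the winning chain, then runs
#' full-spectrum PLS plus each requested selection method and tabulates the
#' retained wavelength count (N.W), chosen nLVs, RMSECV and R^2 per method.
#'
#' @param calibration A labelled [spectra_set()] of calibration samples.
#' @param spec The pretreatment chain to apply (a [preprocessing_spec()]).
#' @param methods Character subset of `c("mw_pls", "mc_uve", "irf")`.
#' @param scheme CV scheme used for the per-method reporting (and inside the
#'   selection searches).
#' @param max_nlvs Latent-variable cap.
#' @param seed Integer seed; per-method substreams are derived from it.
#' @param mw_widths Window widths for [mw_pls()].
#' @param uve_runs,uve_fraction Monte-Carlo settings for [mc_uve()].
#' @param irf_width,irf_iterations Settings for [interval_random_frog()].
#' @param drop_edges Drop Savitzky-Golay edge-flagged channels before
#'   selection (default FALSE).
#' @return List with `table` (tibble: `method`, `n_wavelengths`, `nlvs`,
#'   `rmsecv`, `r2`), `selected` (named list of channel index vectors) and
#'   the `fitted` preprocessor.
#' @export
compare_selection_methods <- function(calibration, spec,
                                      methods = c("mw_pls", "mc_uve", "irf"),
                                      scheme = cv_kfold(5), max_nlvs = 10,
                                      seed = 1L,
                                      mw_widths = c(50, 100),
                                      uve_runs = 500, uve_fraction = 0.8,
                                      irf_width = 20, irf_iterations = 1000,
                                      drop_edges = FALSE) {
  stopifnot(inherits(calibration, "spectra_set"))
  if (length(methods) > 0) methods <- match.arg(methods, several.ok = TRUE)
  fitted <- fit_preprocessor(spec, calibration)
  m <- apply_preprocessor(fitted, calibration$absorbance)
  keep <- seq_len(ncol(m))
  if (drop_edges) keep <- which(!(attr(m, "edge") %||% rep(FALSE, ncol(m))))
  m <- m[, keep, drop = FALSE]
  y <- calibration$meta$fraction
  p <- ncol(m)

  full_cv <- cross_validate(m, y, max_nlvs = max_nlvs, scheme = scheme)
  tab <- tibble::tibble(method = "Full spectrum", n_wavelengths = p,
                        nlvs = full_cv$chosen_nlvs, rmsecv = full_cv$rmsecv,
                        r2 = full_cv$r2)
  selected <- list("Full spectrum" = keep)

  score <- function(vars) {
    cv <- cross_validate(m[, vars, drop = FALSE], y,
                         max_nlvs = min(max_nlvs, length(vars)),
                         scheme = scheme)
    list(cv = cv, vars = vars)
  }
  add_row <- function(name, sc) {
    tab <<- dplyr::bind_rows(tab, tibble::tibble(
      method = name, n_wavelengths = length(sc$vars),
      nlvs = sc$cv$chosen_nlvs, rmsecv = sc$cv$rmsecv, r2 = sc$cv$r2))
    selected[[name]] <<- keep[sc$vars]
  }
  if ("mw_pls" %in% methods) {
    mw <- mw_pls(m, y, widths = pmin(mw_widths, p), scheme = scheme,
                 max_nlvs = max_nlvs)
    add_row("MW-PLS", score(mw$selected))
  }
  if ("mc_uve" %in% methods) {
    uve <- mc_uve(m, y, n_runs = uve_runs, sampling_fraction = uve_fraction,
                  nlvs = full_cv$chosen_nlvs, cutoff_rule = "quantile_scan",
                  seed = as.integer(seed) + 2000L, scheme = scheme)
    add_row("MC-UVE", score(uve$selected))
  }
  if ("irf" %in% methods) {
    irf <- interval_random_frog(m, y, interval_width = min(irf_width, p),
                                n_iterations = irf_iterations,
                                nlvs_cap = max_nlvs,
                                seed = as.integer(seed) + 3000L,
                                scheme = scheme)
    vars <- select_intervals_by_probability(irf, m, y, scheme = scheme,
                                            nlvs_cap = max_nlvs)
    add_row("iRF", score(as.integer(vars)))
  }
  list(table = tab, selected = selected, fitted = fitted)
}

#' Pipeline configuration
#'
#' Assembles (or reads from YAML) the configuration driving [run_study()]:
#' the simulation block (axis length, design, noise), the split rule, the
#' candidate pretreatment chains, per-stage CV schemes, the selection methods
#' with their settings, and the master seed from which every stage derives a
#' named substream (simulate: `seed`; split: `seed + 1000`; MC-UVE:
#' `seed + 2000`; iRF: `seed + 3000`).
#'
#' @param n_points Axis length (default the full 7467-point axis).
#' @param noise List overriding [noise_model()] arguments.
#' @param candidates Character vector of chain names (default all nine).
#' @param screen_on `"calibration"` (leakage-free default) or `"all"`
#'   (whole-set screening).
#' @param screen_kfold Folds for the screening CV.
#' @param selection_methods Subset of `c("mw_pls", "mc_uve", "irf")`.
#' @param selection_kfold Folds for CV inside selection searches.
#' @param final_cv `"loo"` or `"kfold"` for the final model's nLV choice.
#' @param max_nlvs Latent-variable cap.
#' @param mw_widths,uve_runs,uve_fraction,irf_width,irf_iterations Method
#'   settings (see [compare_selection_methods()]).
#' @param pure_adulterant Split handling of 100 % samples.
#' @param seed Master seed.
#' @return A `pipeline_config` (named list).
#' @export
pipeline_config <- function(n_points = 7467,
                            noise = list(),
                            candidates = names(standard_chains()),
                            screen_on = c("calibration", "all"),
                            screen_kfold = 21,
                            selection_methods = c("mw_pls", "mc_uve", "irf"),
                            selection_kfold = 5,
                            final_cv = c("loo", "kfold"),
                            max_nlvs = 10,
                            mw_widths = c(50, 100),
                            uve_runs = 500, uve_fraction = 0.8,
                            irf_width = 20, irf_iterations = 1000,
                            pure_adulterant = c("split", "exclude"),
                            seed = 1L) {
  structure(list(
    n_points = as.integer(n_points), noise = noise,
    candidates = candidates, screen_on = match.arg(screen_on),
    screen_kfold = as.integer(screen_kfold),
    selection_methods = selection_methods,
    selection_kfold = as.integer(selection_kfold),
    final_cv = match.arg(final_cv), max_nlvs = as.integer(max_nlvs),
    mw_widths = as.integer(mw_widths),
    uve_runs = as.integer(uve_runs), uve_fraction = uve_fraction,
    irf_width = as.integer(irf_width),
    irf_iterations = as.integer(irf_iterations),
    pure_adulterant = match.arg(pure_adulterant),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose top-level keys are `pipeline_config()`
#'   arguments.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("unknown config key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full adulteration-quantification study
#'
#' Executes the complete workflow: simulate the labelled mixture spectra,
#' split them per level into calibration and test subsets, screen the
#' candidate pretreatment chains, compare the wavelength-selection methods on
#' the preprocessed calibration set, fit the final PLS model on the best
#' method's channels, and evaluate it on the held-out test set. Rerunning
#' with the same configuration reproduces every number bit-identically.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, all tables are written
#'   via [write_report()] together with per-channel selection profiles.
#' @param data Optional pre-built labelled [spectra_set()] (e.g. loaded with
#'   [read_spectra()]); when supplied the simulate stage is skipped.
#' @return A `study_report`: `preprocessing_table`, `winner` chain name,
#'   `selection_table`, `best_method`, `selected` channel indices per method,
#'   `final` ([evaluate()] report), and a `provenance` block (config hash,
#'   seed, package version).
#' @export
run_study <- function(config = pipeline_config(), output_dir = NULL,
                      data = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dataset <- stage("simulate", {
    if (!is.null(data)) data else {
      nm <- do.call(noise_model, c(config$noise,
                                   if (is.null(config$noise$seed))
                                     list(seed = config$seed)))
      simulate_spectra(default_design(), noise = nm,
                       wavenumber = wavenumber_axis(config$n_points))
    }
  })
  split <- stage("split", split_train_test(
    dataset, pure_adulterant = config$pure_adulterant,
    seed = config$seed + 1000L))
  cal <- split$calibration

  screen_set <- if (config$screen_on == "all") {
    filter_samples(dataset, subset != "unassigned")
  } else cal
  chains <- purrr::map(config$candidates, chain_by_name)
  names(chains) <- config$candidates
  pre_tab <- stage("screen", screen_preprocessing(
    screen_set, chains, scheme = cv_kfold(config$screen_kfold,
                                          seed = config$seed + 1000L),
    max_nlvs = config$max_nlvs))
  winner <- pre_tab$method[1]

  sel <- stage("select", compare_selection_methods(
    cal, chain_by_name(winner), methods = config$selection_methods,
    scheme = cv_kfold(config$selection_kfold, seed = config$seed + 1000L),
    max_nlvs = config$max_nlvs, seed = config$seed,
    mw_widths = config$mw_widths, uve_runs = config$uve_runs,
    uve_fraction = config$uve_fraction, irf_width = config$irf_width,
    irf_iterations = config$irf_iterations))
  best_i <- order(sel$table$rmsecv, sel$table$n_wavelengths)[1]
  best_method <- sel$table$method[best_i]

  final <- stage("fit/evaluate", {
    vars <- sel$selected[[best_method]]
    m_cal <- apply_preprocessor(sel$fitted, cal$absorbance)[, vars, drop = FALSE]
    final_scheme <- if (config$final_cv == "loo") cv_loo()
      else cv_kfold(config$selection_kfold, seed = config$seed + 1000L)
    cv <- cross_validate(m_cal, cal$meta$fraction,
                         max_nlvs = min(config$max_nlvs, length(vars)),
                         scheme = final_scheme)
    model <- fit_pls(m_cal, cal$meta$fraction, cv$chosen_nlvs)
    list(cv = cv,
         eval = evaluate(model, sel$fitted, cal, split$test, variables = vars))
  })

  report <- structure(list(
    preprocessing_table = pre_tab,
    winner = winner,
    selection_table = sel$table,
    best_method = best_method,
    selected = sel$selected,
    final_cv = glance(final$cv),
    final = final$eval,
    provenance = list(config_hash = rlang::hash(unclass(config)),
                      seed = config$seed,
                      package_version = as.character(
                        utils::packageVersion("ftirquant")))
  ), class = "study_report")

  if (!is.null(output_dir)) {
    write_report(report, output_dir)
    prof <- tibble::tibble(
      index = seq_len(n_wavenumbers(cal)),
      wavenumber = cal$wavenumber
    )
    for (nm in names(sel$selected)) {
      prof[[gsub("[^A-Za-z0-9]", "_", nm)]] <-
        prof$index %in% sel$selected[[nm]]
    }
    readr::write_delim(prof, file.path(output_dir, "selected_wavenumbers.tsv"),
                       delim = "\t")
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  best pretreatment: %s (RMSECV %.4g %%)\n",
              x$winner, x$preprocessing_table$rmsecv[1]))
  cat(sprintf("  best selection:    %s (%d channels)\n", x$best_method,
              length(x$selected[[x$best_method]])))
  cat(sprintf("  final model:       nLVs = %d, RMSEC = %.4g, RMSEP = %.4g %% w/w\n",
              x$final_cv$chosen_nlvs, x$final$rmsec, x$final$rmsep))
  cat(sprintf("  R2: cal %.4f / test %.4f\n", x$final$r2_cal, x$final$r2_test))
  invisible(x)
}

#' @importFrom generics glance
#' @export
glance.study_report <- function(x, ...) {
  tibble::tibble(
    winner_chain = x$winner,
    best_method = x$best_method,
    n_selected = length(x$selected[[x$best_method]]),
    nlvs = x$final_cv$chosen_nlvs,
    rmsecv = x$final_cv$rmsecv,
    rmsec = x$final$rmsec,
    rmsep = x$final$rmsep,
    r2_cal = x$final$r2_cal,
    r2_test = x$final$r2_test
  )
}
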