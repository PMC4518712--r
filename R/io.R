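#' Write a sedimentation-equilibrium experiment to disk
#'
#' One CSV per channel (`radius_cm,signal`) plus a YAML manifest holding the
#' per-channel metadata (rotor speed, loading signal, geometry, noise) and
#' the shared solution properties. If the experiment carries a generating
#' truth (from [gen_se()]) it is written to a `truth.yaml` sidecar.
#'
#' @param experiment an [se_experiment()].
#' @param dir output directory (created if needed).
#' @return Path to the manifest file, invisibly.
#' @export
write_se_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chan_meta <- list()
  for (i in seq_along(experiment$channels)) {
    ch <- experiment$channels[[i]]
    fname <- sprintf("channel_%02d.csv", i)
    utils::write.csv(data.frame(radius_cm = ch$radii, signal = ch$signal),
                     file.path(dir, fname), row.names = FALSE)
    chan_meta[[i]] <- list(file = fname, rotor_speed_rpm = ch$rotor_speed,
                           loading_signal = ch$loading_signal,
                           meniscus_cm = ch$meniscus, bottom_cm = ch$bottom,
                           noise_sigma = ch$noise_sigma)
  }
  p <- experiment$properties
  manifest <- list(
    properties = list(monomer_mass = p$monomer_mass, vbar = p$vbar,
                      density = p$density, viscosity = p$viscosity,
                      molar_signal = p$molar_signal,
                      pathlength = p$pathlength,
                      temperature = p$temperature),
    scheme = as.integer(experiment$scheme$stoichiometries),
    channels = chan_meta)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  truth <- attr(experiment, "truth")
  if (!is.null(truth)) yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(path)
}

#' Read a sedimentation-equilibrium experiment from a manifest
#'
#' @param manifest path to a `manifest.yaml` written by
#'   [write_se_experiment()].
#' @param scheme optional [association_scheme()] overriding the manifest's
#'   stoichiometries (the manifest stores no constants; fitting starts from
#'   the scheme given here).
#' @return An [se_experiment()].
#' @export
read_se_experiment <- function(manifest, scheme = NULL) {
  if (!file.exists(manifest)) stop("file not found: ", manifest)
  m <- yaml::read_yaml(manifest)
  dir <- dirname(manifest)
  pr <- m$properties
  props <- solution_properties(pr$monomer_mass, pr$vbar, pr$density,
                               pr$viscosity, pr$molar_signal, pr$pathlength,
                               pr$temperature)
  channels <- lapply(m$channels, function(cm) {
    tab <- utils::read.csv(file.path(dir, cm$file))
    se_channel(tab$radius_cm, tab$signal, cm$rotor_speed_rpm,
               cm$loading_signal, cm$meniscus_cm, cm$bottom_cm,
               cm$noise_sigma)
  })
  if (is.null(scheme)) {
    sto <- as.integer(m$scheme)
    ## placeholder constants; replaced during fitting
    scheme <- association_scheme(sto, rep(1e-6, length(sto) - 1L))
  }
  se_experiment(channels, props, scheme)
}

## "# key: value" header helpers for the small delimited formats.
write_kv_header <- function(con, kv) {
  for (k in names(kv)) writeLines(sprintf("# %s: %s", k, kv[[k]]), con)
}
read_kv_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1L]]
    if (length(m) == 3L) kv[[trimws(m[2L])]] <- trimws(m[3L])
  }
  kv
}

#' Write / read an MST series file
#'
#' Plain-text format: `# key: value` header lines (labeled protein
#' concentration, and the generating truth when present) followed by a CSV
#' table `conc_nM,fnorm`.
#'
#' @param series an [mst_series()].
#' @param path file path.
#' @return `path` invisibly (writer); an [mst_series()] (reader).
#' @export
write_mst_series <- function(series, path) {
  con <- file(path, "w"); on.exit(close(con))
  hdr <- list(labeled_nM = series$labeled_total)
  truth <- attr(series, "truth")
  if (!is.null(truth)) {
    hdr$truth_kd_M <- truth$kd
    hdr$truth_model <- truth$model_tag
    hdr$seed <- truth$seed
  }
  write_kv_header(con, hdr)
  writeLines("conc_nM,fnorm", con)
  writeLines(sprintf("%.10g,%.10g", series$titrant_total, series$fnorm), con)
  invisible(path)
}

#' @rdname write_mst_series
#' @export
read_mst_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  kv <- read_kv_header(path)
  if (is.null(kv$labeled_nM)) stop("MST file lacks a labeled_nM header: ", path)
  tab <- utils::read.csv(path, comment.char = "#")
  mst_series(tab$conc_nM, as.numeric(kv$labeled_nM), tab$fnorm)
}

#' Write / read an ITC titration file
#'
#' Plain-text format: `# key: value` header (cell volume, concentrations,
#' temperature, truth when present) followed by a CSV table
#' `inj_ul,heat_ucal`.
#'
#' @param exp an [itc_experiment()] with heats.
#' @param path file path.
#' @return `path` invisibly (writer); an [itc_experiment()] (reader).
#' @export
write_itc_experiment <- function(exp, path) {
  con <- file(path, "w"); on.exit(close(con))
  hdr <- list(cell_volume_ul = exp$cell_volume, cell_uM = exp$cell_conc,
              syringe_uM = exp$syringe_conc, temperature_K = exp$temperature)
  truth <- attr(exp, "truth")
  if (!is.null(truth)) {
    hdr$truth_kd_M <- truth$kd; hdr$truth_dH_kJmol <- truth$dH
    hdr$truth_N <- truth$n_stoich; hdr$seed <- truth$seed
  }
  write_kv_header(con, hdr)
  writeLines("inj_ul,heat_ucal", con)
  writeLines(sprintf("%.10g,%.10g", exp$injection_volumes, exp$heats), con)
  invisible(path)
}

#' @rdname write_itc_experiment
#' @export
read_itc_experiment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  kv <- read_kv_header(path)
  need <- c("cell_volume_ul", "cell_uM", "syringe_uM", "temperature_K")
  if (!all(need %in% names(kv)))
    stop("ITC file header incomplete (need ", paste(need, collapse = ", "),
         "): ", path)
  tab <- utils::read.csv(path, comment.char = "#")
  itc_experiment(as.numeric(kv$cell_volume_ul), as.numeric(kv$cell_uM),
                 as.numeric(kv$syringe_uM), tab$inj_ul, tab$heat_ucal,
                 as.numeric(kv$temperature_K))
}

## Flatten a fit object into a deterministic key/value/units table.
report_table <- function(result, seed = NA) {
  if (inherits(result, "se_fit")) {
    rows <- list(c("model", paste(result$scheme, collapse = "-"), ""))
    for (i in seq_along(result$kd_estimates)) {
      n <- result$scheme[i + 1L]
      rows <- c(rows, list(
        c(sprintf("kd_%dmer", n), sprintf("%.6g", result$kd_estimates[i]),
          sprintf("M^%d", n - 1L))))
      if (!is.null(result$kd_ci))
        rows <- c(rows, list(
          c(sprintf("kd_%dmer_ci_lower", n),
            sprintf("%.6g", result$kd_ci[i, 1L]), sprintf("M^%d", n - 1L)),
          c(sprintf("kd_%dmer_ci_upper", n),
            sprintf("%.6g", result$kd_ci[i, 2L]), sprintf("M^%d", n - 1L))))
    }
    rows <- c(rows, list(
      c("reduced_chi2", sprintf("%.6g", result$reduced_chi2), ""),
      c("rmsd_min", sprintf("%.6g", min(result$rmsd_per_channel)), "AU"),
      c("rmsd_max", sprintf("%.6g", max(result$rmsd_per_channel)), "AU"),
      c("n_monte_carlo", sprintf("%d", result$n_monte_carlo), ""),
      c("ci_level", sprintf("%.3g", result$ci_level), "")))
  } else if (inherits(result, "mst_fit")) {
    rows <- list(
      c("model", result$model_tag, ""),
      c("kd", sprintf("%.6g", result$kd), "M"),
      c("f_free", sprintf("%.6g", result$f_free), "per-mil"),
      c("f_bound", sprintf("%.6g", result$f_bound), "per-mil"),
      c("residual_rms", sprintf("%.6g", result$residual_rms), "per-mil"))
    if (!is.null(result$kd_ci))
      rows <- c(rows, list(
        c("kd_ci_lower", sprintf("%.6g", result$kd_ci[1L]), "M"),
        c("kd_ci_upper", sprintf("%.6g", result$kd_ci[2L]), "M")))
  } else if (inherits(result, "itc_fit")) {
    th <- result$thermo
    rows <- list(
      c("model", "one_site", ""),
      c("kd", sprintf("%.6g", th$kd), "M"),
      c("dG", sprintf("%.6g", th$dG), "kJ/mol"),
      c("dH", sprintf("%.6g", th$dH), "kJ/mol"),
      c("TdS", sprintf("%.6g", th$TdS), "kJ/mol"),
      c("N", sprintf("%.6g", th$n_stoich), ""),
      c("temperature", sprintf("%.6g", th$temperature), "K"),
      c("q_dilution", sprintf("%.6g", result$q_dilution), "ucal"),
      c("residual_rms", sprintf("%.6g", result$residual_rms), "ucal"),
      c("c_value", sprintf("%.6g", result$c_value), ""))
  } else stop("no report writer for class ", paste(class(result), collapse = "/"))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("parameter", "value", "units")
  df
}

#' Write a fit report
#'
#' Writes a machine-readable tab-delimited table (`<stem>.tsv`) with
#' deterministic field order and a human-readable summary (`<stem>.txt`).
#' The seed used for the run is echoed in the header of both files.
#'
#' @param result an `se_fit`, `mst_fit` or `itc_fit`.
#' @param stem output path stem (without extension).
#' @param seed seed to record in the headers.
#' @return Character vector of the two paths, invisibly.
#' @export
write_report <- function(result, stem, seed = NA) {
  tab <- report_table(result)
  tsv <- paste0(stem, ".tsv"); txt <- paste0(stem, ".txt")
  con <- file(tsv, "w")
  writeLines(sprintf("# assocfit report; seed: %s", seed), con)
  writeLines(paste(names(tab), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(tab), sep = "\t")), con)
  close(con)
  con <- file(txt, "w")
  writeLines(sprintf("assocfit report (seed %s)", seed), con)
  sink(con); print(result); sink()
  close(con)
  invisible(c(tsv, txt))
}

#' Write a constraint-audit report
#'
#' @param report a `constraint_report` from [audit_constraints()].
#' @param stem output path stem.
#' @param seed seed to record in the header.
#' @return Character vector of the two paths, invisibly.
#' @export
write_audit_report <- function(report, stem, seed = NA) {
  tsv <- paste0(stem, ".tsv"); txt <- paste0(stem, ".txt")
  con <- file(tsv, "w")
  writeLines(sprintf("# assocfit audit; seed: %s; overall: %s", seed,
                     if (attr(report, "overall_pass")) "PASS" else "FAIL"),
             con)
  utils::write.table(report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  con <- file(txt, "w")
  sink(con); print(report); sink()
  close(con)
  invisible(c(tsv, txt))
}
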