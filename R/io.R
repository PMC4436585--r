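# atomic file write: write to a temp file in the same directory, then rename
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("atomic rename failed for ", path)
  invisible(path)
}

#' Write a trace family as a TSV trace bundle
#'
#' Plain-text bundle: header lines `#key<TAB>value` carrying acquisition
#' metadata (sampling_kHz, holding_mV, levels_mV comma-list, epochs, units
#' pA/ms), then a tab-separated table with `time_ms` and one `sweep_NNN`
#' column per level. Writing is atomic (temp file + rename).
#'
#' @param family a `trace_family`.
#' @param path output file path.
#' @param extra named character vector of additional header keys.
#' @return the path, invisibly.
#' @export
write_trace_bundle <- function(family, path, extra = NULL) {
  proto <- family$protocol
  hdr <- c(sampling_kHz = proto$sampling_kHz,
           filter_kHz = proto$filter_kHz,
           holding_mV = proto$holding_mV,
           tail_mV = proto$tail_mV,
           pre_ms = proto$pre_ms, step_ms = proto$step_ms,
           tail_ms = proto$tail_ms,
           levels_mV = paste(proto$levels_mV, collapse = ","),
           units = "pA/ms")
  if (!is.null(extra)) hdr <- c(hdr, extra)
  tab <- data.frame(time_ms = family$time_ms, family$sweeps)
  names(tab) <- c("time_ms",
                  sprintf("sweep_%03d", seq_len(ncol(family$sweeps)) - 1))
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w"); on.exit(close(con))
    writeLines(paste0("#", names(hdr), "\t", hdr), con)
    utils::write.table(format(tab, digits = 12, scientific = FALSE,
                              trim = TRUE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

#' Read a TSV trace bundle
#'
#' Inverse of [write_trace_bundle()]: lossless round trip of the numeric
#' content to better than 1e-9 relative. Unknown header keys are accepted
#' and preserved in `meta$header`.
#'
#' @param path bundle file path.
#' @return a `trace_family` (with an empty `truth` sidecar).
#' @export
read_trace_bundle <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr_lines <- lines[is_hdr]
  kv <- strsplit(sub("^#", "", hdr_lines), "\t", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed header line: ", hdr_lines[which(bad)[1]])
  hdr <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  for (key in c("sampling_kHz", "levels_mV", "units"))
    if (!key %in% names(hdr))
      stop("trace bundle missing mandatory header key: ", key)
  body <- lines[!is_hdr]
  cols <- strsplit(body, "\t", fixed = TRUE)
  ncols <- length(cols[[1]])
  badrow <- which(vapply(cols[-1], length, 1L) != ncols)
  if (length(badrow) > 0)
    stop("truncated column in data row ", badrow[1])
  header_names <- cols[[1]]
  vals <- vapply(cols[-1], function(x) as.numeric(x), numeric(ncols))
  mat <- t(vals)
  colnames(mat) <- header_names
  levels <- as.numeric(strsplit(hdr[["levels_mV"]], ",")[[1]])
  get_num <- function(k, default) if (k %in% names(hdr))
    as.numeric(hdr[[k]]) else default
  proto <- voltage_protocol(
    holding_mV = get_num("holding_mV", 0),
    levels_mV = levels,
    pre_ms = get_num("pre_ms", 1), step_ms = get_num("step_ms", 1),
    tail_ms = get_num("tail_ms", 1),
    tail_mV = get_num("tail_mV", get_num("holding_mV", 0)),
    sampling_kHz = as.numeric(hdr[["sampling_kHz"]]),
    filter_kHz = get_num("filter_kHz", 3))
  structure(list(protocol = proto, time_ms = mat[, 1],
                 sweeps = mat[, -1, drop = FALSE],
                 meta = list(header = hdr, cell = NULL),
                 truth = NULL),
            class = "trace_family")
}

#' Write the ground-truth sidecar of a synthetic object as TSV
#'
#' @param truth a data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth_sidecar <- function(truth, path) {
  atomic_write(path, function(tmp)
    utils::write.table(truth, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE))
}

#' Write a vesicle scene as a multi-page 16-bit TIFF
#'
#' Page order 405, 488, 561. Intensities are scaled by `scale` counts per
#' unit into the 16-bit range; the scale is recorded so reading restores
#' the original values. A ground-truth TSV sidecar (`<path>.truth.tsv`) is
#' written alongside (x_px, y_px with pixel centers at integer coordinates,
#' origin top-left, row-major).
#'
#' @param scene a `vesicle_scene`.
#' @param path output TIFF path.
#' @param scale counts per intensity unit (default 1).
#' @return the path, invisibly.
#' @export
write_scene_tiff <- function(scene, path, scale = 1) {
  pages <- lapply(scene$channels[c("ch405", "ch488", "ch561")], function(m) {
    v <- round(m * scale)
    if (any(v < 0) || any(v > 65535)) stop("intensity out of 16-bit range")
    v / 65535
  })
  atomic_write(path, function(tmp)
    tiff::writeTIFF(pages, tmp, bits.per.sample = 16L))
  write_truth_sidecar(scene$truth, paste0(path, ".truth.tsv"))
  invisible(path)
}

#' Read a multi-page TIFF scene
#'
#' @param path TIFF path (page order 405, 488, 561).
#' @param scale counts per intensity unit used at write time.
#' @return named list of matrices `ch405`, `ch488`, `ch561`.
#' @export
read_scene_tiff <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 3) stop("expected a 3-page TIFF (405, 488, 561)")
  ch <- lapply(pages[1:3], function(p) round(p * 65535) / scale)
  names(ch) <- c("ch405", "ch488", "ch561")
  ch
}

#' Read a flat sectioned key = value config file
#'
#' Format: `[section]` headers with `key = value` lines; `#` comments and
#' blank lines ignored. Values are parsed as numeric where possible.
#'
#' @param path config file path.
#' @param known optional named list of allowed keys per section; unknown
#'   keys raise an error when given.
#' @return nested named list (sections of key-value pairs).
#' @export
read_run_config <- function(path, known = NULL) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list(); section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
      if (!is.null(known)) {
        if (!section %in% names(known) || !key %in% known[[section]])
          stop("unknown config key: [", section, "] ", key)
      }
      num <- suppressWarnings(as.numeric(val))
      out[[section]][[key]] <- if (!is.na(num)) num else val
    } else stop("unparseable config line: ", ln)
  }
  out
}

#' Write a resolved config echo
#'
#' @param config nested named list as from [read_run_config()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_run_config <- function(config, path) {
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w"); on.exit(close(con))
    for (sec in names(config)) {
      writeLines(paste0("[", sec, "]"), con)
      for (key in names(config[[sec]]))
        writeLines(paste0(key, " = ", config[[sec]][[key]]), con)
    }
  })
}

#' Run a simulate-and-analyze pipeline from a config
#'
#' Umbrella driver: for each requested stage, simulates the preset
#' construct's data and runs the matching analysis, writing TSV outputs and
#' a resolved-config echo into the output directory. Deterministic given
#' the seed; all writes are atomic.
#'
#' Stages: `gating` (trace family -> I-V, off-charges, Boltzmann fit of
#' Q(V), Q/I at +165 mV) and `capacitance` (sine-plus-DC sweeps -> Cm(V),
#' non-linear capacitance, derivative-of-Boltzmann fit).
#'
#' @param config list with `global` (seed, out_dir, construct) and optional
#'   per-stage sections; see [read_run_config()].
#' @param stages character vector of stages to run.
#' @return output directory, invisibly; stops before writing anything on an
#'   invalid stage name.
#' @export
run_pipeline <- function(config, stages = c("gating", "capacitance")) {
  bad <- setdiff(stages, c("gating", "capacitance"))
  if (length(bad) > 0) stop("invalid stage name: ", paste(bad, collapse = ", "))
  g <- config$global
  if (is.null(g$seed) || is.null(g$out_dir))
    stop("config must provide [global] seed and out_dir")
  construct <- if (is.null(g$construct)) "WT" else g$construct
  preset <- clc5_preset(construct)
  dir.create(g$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(g$seed)

  if ("gating" %in% stages) {
    proto <- make_step_protocol(-60, -115, 175, 20, 20, 100, 50, 100)
    fam <- simulate_trace_family(proto, preset$cell, preset$gating,
                                 preset$transport, noise_sd_pA = 5,
                                 seed = seed)
    write_trace_bundle(fam, file.path(g$out_dir, "traces.tsv"))
    q <- family_off_charges(fam)
    iv <- build_iv(list(fam))
    fit <- fit_boltzmann_q(q$V_mV, q$Q_off_pC)
    res <- data.frame(V_mV = q$V_mV, Q_off_pC = q$Q_off_pC,
                      I_ss_pA = iv$I_mean)
    write_truth_sidecar(res, file.path(g$out_dir, "gating_results.tsv"))
    fitsum <- data.frame(param = c("Qmax_pC", "V05_mV", "z_delta"),
                         value = c(fit$Qmax_pC, fit$V05_mV, fit$z_delta),
                         se = unname(fit$se))
    write_truth_sidecar(fitsum, file.path(g$out_dir, "gating_fit.tsv"))
  }
  if ("capacitance" %in% stages) {
    rec <- simulate_sine_dc_recording(seq(-105, 245, by = 10), preset$cell,
                                      preset$gating,
                                      cap_V05_mV = preset$cap_V05_mV,
                                      noise_sd_pA = 5, seed = seed + 1)
    cs <- capacitance_sweep(rec)
    dc <- nonlinear_capacitance(cs)
    out <- cbind(cs, dC_pF = dc$dC_pF)
    write_truth_sidecar(out, file.path(g$out_dir, "capacitance.tsv"))
    fit <- fit_dboltzmann_c(dc$V_dc_mV, dc$dC_pF)
    fitsum <- data.frame(param = c("Qmax_pC", "V05_mV", "z_delta",
                                   "no_peak_in_range"),
                         value = c(fit$Qmax_pC, fit$V05_mV, fit$z_delta,
                                   as.numeric(fit$no_peak_in_range)))
    write_truth_sidecar(fitsum, file.path(g$out_dir, "capacitance_fit.tsv"))
  }
  write_run_config(config, file.path(g$out_dir, "config_echo.txt"))
  invisible(g$out_dir)
}
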