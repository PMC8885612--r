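# File names of the published case-directory layout. All continuous
# channels are two-column CSVs (time_s, value); times are seconds since
# the defibrillator was switched on.
CASE_FILES <- list(
  accel = "Accelerometer.csv",
  ecg_pads = "ShockElectrodes.csv",
  capno = "Capnography.csv",
  physio = "PhysioStatus.csv",
  ann_periods = "Ann_CC-periods.csv",
  defib_events = "DefibrillationEvents.csv",
  alg_periods = "Alg_CC-periods.csv"
)

# internal: strict numeric CSV reader. Deposited files are expected to use
# the documented headers; a file with the right arity but other labels is
# mapped positionally (the header alias escape hatch for external
# exports), with a warning. Any unparseable numeric cell is fatal, with
# its row index.
read_channel_csv <- function(path, cols) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (!all(cols %in% names(raw))) {
    if (ncol(raw) < length(cols)) {
      abort(sprintf(
        "%s: expected columns %s", basename(path), paste(cols, collapse = ", ")
      ))
    }
    warn(sprintf(
      "%s: columns %s not found; reading the first %d columns positionally",
      basename(path), paste(cols, collapse = ", "), length(cols)
    ))
    raw <- raw[, seq_along(cols)]
    names(raw) <- cols
  }
  out <- raw[cols]
  for (nm in cols) {
    x <- suppressWarnings(as.numeric(out[[nm]]))
    bad <- which(is.na(x) & !is.na(out[[nm]]))
    if (length(bad) > 0L) {
      abort(sprintf(
        "%s: unparseable numeric value %s in column %s, row %d",
        basename(path), out[[nm]][bad[1L]], nm, bad[1L]
      ))
    }
    out[[nm]] <- x
  }
  as_tibble(out)
}

read_channel <- function(dir, file, fs_nominal) {
  path <- file.path(dir, file)
  df <- read_channel_csv(path, c("time_s", "value"))
  tr <- tryCatch(
    as_trace(t = df$time_s, v = df$value, fs_nominal = fs_nominal),
    error = function(e) abort(sprintf("%s: %s", file, conditionMessage(e)))
  )
  tr
}

#' Read a resuscitation case directory
#'
#' Reads the published case layout: `Accelerometer.csv` (250 Hz, internal
#' units; required), `ShockElectrodes.csv` (250 Hz, mV), `Capnography.csv`
#' (125 Hz, mmHg), `PhysioStatus.csv` (Arrest and ROSC/Termination
#' timepoints), `Ann_CC-periods.csv` (annotated compression periods) and
#' `DefibrillationEvents.csv` (shock time, energy, impedance). Optional
#' files that are absent yield `NULL` fields with a warning. Channels are
#' returned exactly as stored: never reordered, re-based or resampled.
#'
#' @param case_dir Path to the case directory.
#' @return A `cc_case` object: a list with elements `accel`, `ecg_pads`,
#'   `capno` (trace tibbles or `NULL`), `physio` (tibble `label`, `time_s`),
#'   `ann_periods` (segmentation tibble or `NULL`), `defib_events` (tibble
#'   or `NULL`) and `path`.
#' @seealso [write_case()], [detect_compressions()]
#' @export
read_case <- function(case_dir) {
  if (!dir.exists(case_dir)) abort(sprintf("no such case directory: %s", case_dir))
  if (!file.exists(file.path(case_dir, CASE_FILES$accel))) {
    abort("no accelerometer channel")
  }
  accel <- read_channel(case_dir, CASE_FILES$accel, fs_nominal = 250)

  opt_channel <- function(key, fs) {
    path <- file.path(case_dir, CASE_FILES[[key]])
    if (!file.exists(path)) {
      warn(sprintf("%s absent; continuing without it", CASE_FILES[[key]]))
      return(NULL)
    }
    read_channel(case_dir, CASE_FILES[[key]], fs_nominal = fs)
  }
  ecg_pads <- opt_channel("ecg_pads", 250)
  capno <- opt_channel("capno", 125)

  physio <- NULL
  physio_path <- file.path(case_dir, CASE_FILES$physio)
  if (file.exists(physio_path)) {
    raw <- readr::read_csv(physio_path,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE, show_col_types = FALSE
    )
    if (!all(c("label", "time_s") %in% names(raw))) {
      abort("PhysioStatus.csv: expected columns label, time_s")
    }
    physio <- tibble(
      label = raw$label,
      time_s = suppressWarnings(as.numeric(raw$time_s))
    )
    if (anyNA(physio$time_s)) abort("PhysioStatus.csv: unparseable time value")
    bad <- setdiff(unique(physio$label), c("Arrest", "ROSC/Termination"))
    if (length(bad) > 0L) {
      abort(sprintf("PhysioStatus.csv: unknown label %s", bad[1L]))
    }
    check_physio_pairing(physio)
  } else {
    warn("PhysioStatus.csv absent; continuing without it")
  }

  ann_periods <- NULL
  ann_path <- file.path(case_dir, CASE_FILES$ann_periods)
  if (file.exists(ann_path)) {
    ann_periods <- read_segmentation(ann_path)
    rng <- range(accel$t)
    if (nrow(ann_periods) > 0L &&
      (min(ann_periods$start_s) < rng[1L] - 1e-9 ||
        max(ann_periods$stop_s) > rng[2L] + 1e-9)) {
      abort("annotated periods lie outside the accelerometer time range")
    }
  } else {
    warn("Ann_CC-periods.csv absent; continuing without it")
  }

  defib_events <- NULL
  defib_path <- file.path(case_dir, CASE_FILES$defib_events)
  if (file.exists(defib_path)) {
    defib_events <- read_channel_csv(
      defib_path, c("time_s", "energy_j", "impedance_ohm")
    )
  }

  new_cc_case(
    accel = accel, ecg_pads = ecg_pads, capno = capno, physio = physio,
    ann_periods = ann_periods, defib_events = defib_events, path = case_dir
  )
}

# Arrest must precede its paired ROSC/Termination, in file order
check_physio_pairing <- function(physio) {
  arrest <- physio$time_s[physio$label == "Arrest"]
  rosc <- physio$time_s[physio$label == "ROSC/Termination"]
  n <- min(length(arrest), length(rosc))
  if (n > 0L && any(arrest[seq_len(n)] >= rosc[seq_len(n)])) {
    abort("PhysioStatus.csv: Arrest time does not precede ROSC/Termination")
  }
  invisible(physio)
}

new_cc_case <- function(accel, ecg_pads = NULL, capno = NULL, physio = NULL,
                        ann_periods = NULL, defib_events = NULL, path = NULL) {
  structure(
    list(
      accel = accel, ecg_pads = ecg_pads, capno = capno, physio = physio,
      ann_periods = ann_periods, defib_events = defib_events, path = path
    ),
    class = "cc_case"
  )
}

#' Write a case to the published directory layout
#'
#' Inverse of [read_case()]: writes each present channel and annotation
#' file into `dir` under its canonical file name. Timestamps are written
#' with millisecond precision, values with six significant digits.
#'
#' @param case A `cc_case` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_case <- function(case, dir) {
  stopifnot(inherits(case, "cc_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_channel <- function(trace, file) {
    df <- data.frame(
      time_s = sprintf("%.4f", trace$t),
      value = sprintf("%.6g", trace$v)
    )
    readr::write_csv(df, file.path(dir, file))
  }
  write_channel(case$accel, CASE_FILES$accel)
  if (!is.null(case$ecg_pads)) write_channel(case$ecg_pads, CASE_FILES$ecg_pads)
  if (!is.null(case$capno)) write_channel(case$capno, CASE_FILES$capno)
  if (!is.null(case$physio)) {
    readr::write_csv(
      data.frame(label = case$physio$label,
                 time_s = sprintf("%.4f", case$physio$time_s)),
      file.path(dir, CASE_FILES$physio)
    )
  }
  if (!is.null(case$ann_periods)) {
    write_segmentation(case$ann_periods, file.path(dir, CASE_FILES$ann_periods))
  }
  if (!is.null(case$defib_events)) {
    readr::write_csv(case$defib_events, file.path(dir, CASE_FILES$defib_events))
  }
  invisible(dir)
}

#' @export
print.cc_case <- function(x, ...) {
  cat("<cc_case>", if (!is.null(x$path)) x$path else "", "\n")
  rng <- range(x$accel$t)
  cat(sprintf(
    "  accel: %d samples, %.1f-%.1f s, %.1f Hz\n",
    nrow(x$accel), rng[1L], rng[2L], trace_fs(x$accel)
  ))
  for (nm in c("ecg_pads", "capno")) {
    if (!is.null(x[[nm]])) {
      cat(sprintf("  %s: %d samples, %.1f Hz\n",
                  nm, nrow(x[[nm]]), trace_fs(x[[nm]])))
    }
  }
  if (!is.null(x$physio)) {
    cat(sprintf("  physio: %s\n",
                paste(sprintf("%s@%.1fs", x$physio$label, x$physio$time_s),
                      collapse = ", ")))
  }
  if (!is.null(x$ann_periods)) {
    cat(sprintf("  annotations: %d periods\n", nrow(x$ann_periods)))
  }
  invisible(x)
}
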