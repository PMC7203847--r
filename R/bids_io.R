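# BIDS-EEG dataset reading and lossless derivative writing. Raw data files
# are never modified: every pipeline decision is emitted as a sidecar table
# next to a byte-identical copy of (or reference to) the source file.
#
# Supported on-disk dialect: BrainVision (.vhdr/.vmrk/.eeg, IEEE_FLOAT_32 or
# INT_16). Other dialects named by BIDS (EDF, EEGLAB set) are recognized by
# the scanner but rejected at read time with an unsupported-format error;
# converting proprietary sources is an acquisition-site task that sits
# outside the standardized core.

BIDS_EEG_EXT <- c(vhdr = "brainvision", edf = "edf", set = "eeglab")

#' Scan a BIDS-EEG dataset
#'
#' Indexes every EEG data file matching the BIDS naming scheme
#' `sub-<id>/[ses-<id>/]eeg/sub-<id>[_ses-<id>]_task-<label>[_run-<n>]_eeg.<ext>`.
#' Non-conforming files inside eeg/ directories are skipped with a warning.
#'
#' @param root dataset root directory.
#' @return a data.frame manifest (class `dataset_manifest`) with columns
#'   subject, session, task, run, path, format.
#' @export
scan_dataset <- function(root) {
  if (!dir.exists(root)) stopf("scan_dataset: root '%s' does not exist", root)
  subs <- list.dirs(root, recursive = FALSE, full.names = TRUE)
  subs <- subs[grepl("^sub-[A-Za-z0-9]+$", basename(subs))]
  rows <- list()
  for (sd in subs) {
    eeg_dirs <- c(file.path(sd, "eeg"),
                  file.path(list.dirs(sd, recursive = FALSE)[
                    grepl("^ses-", basename(list.dirs(sd, recursive = FALSE)))], "eeg"))
    eeg_dirs <- eeg_dirs[dir.exists(eeg_dirs)]
    if (!length(eeg_dirs)) {
      warnf("scan_dataset: %s has no eeg/ directory; skipped", basename(sd))
      next
    }
    for (ed in eeg_dirs) {
      files <- list.files(ed, pattern = "_eeg\\.(vhdr|edf|set)$", full.names = TRUE)
      other <- setdiff(list.files(ed, pattern = "\\.(vhdr|edf|set)$", full.names = TRUE), files)
      for (f in other) warnf("scan_dataset: non-BIDS file name '%s'; skipped", basename(f))
      for (f in files) {
        ent <- parse_bids_name(basename(f))
        if (is.null(ent)) {
          warnf("scan_dataset: non-BIDS file name '%s'; skipped", basename(f))
          next
        }
        ext <- tolower(tools::file_ext(f))
        rows[[length(rows) + 1L]] <-
          data.frame(subject = ent$sub, session = ent$ses %||% NA_character_,
                     task = ent$task %||% NA_character_,
                     run = ent$run %||% NA_character_,
                     path = f, format = unname(BIDS_EEG_EXT[ext]),
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stopf("scan_dataset: no EEG data files found under '%s'", root)
  man <- do.call(rbind, rows)
  man <- man[order(man$subject, man$session, man$task, man$run), , drop = FALSE]
  rownames(man) <- NULL
  attr(man, "root") <- root
  class(man) <- c("dataset_manifest", "data.frame")
  man
}

parse_bids_name <- function(fname) {
  base <- sub("_eeg\\.[A-Za-z]+$", "", fname)
  if (identical(base, fname)) return(NULL)
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "-", fixed = TRUE)
  if (any(lengths(kv) < 2)) return(NULL)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = "-"), "")
  if (keys[1] != "sub") return(NULL)
  out <- as.list(vals)
  names(out) <- keys
  out
}

bids_base <- function(entry) sub("_eeg\\.[A-Za-z]+$", "", entry$path)

# --- BrainVision dialect ----------------------------------------------------

parse_vhdr <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "latin1")
  section <- ""
  kv <- list(); channels <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    if (grepl("^\\[.*\\]\\s*$", ln)) { section <- gsub("[][]", "", trimws(ln)); next }
    if (!grepl("=", ln, fixed = TRUE)) next
    eq <- regexpr("=", ln, fixed = TRUE)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    if (section == "Channel Infos") channels[[key]] <- val
    else kv[[paste(section, key, sep = ".")]] <- val
  }
  list(kv = kv, channels = channels)
}

read_brainvision <- function(vhdr_path) {
  hd <- parse_vhdr(vhdr_path)
  kv <- hd$kv
  dirn <- dirname(vhdr_path)
  fmt <- toupper(kv[["Common Infos.DataFormat"]] %||% "BINARY")
  if (fmt != "BINARY") stopf("read_recording: BrainVision DataFormat '%s' unsupported", fmt)
  orient <- toupper(kv[["Common Infos.DataOrientation"]] %||% "MULTIPLEXED")
  nch <- as.integer(kv[["Common Infos.NumberOfChannels"]])
  sfreq <- 1e6 / as.numeric(kv[["Common Infos.SamplingInterval"]])
  binfmt <- toupper(kv[["Binary Infos.BinaryFormat"]] %||% "IEEE_FLOAT_32")
  data_file <- file.path(dirn, kv[["Common Infos.DataFile"]])
  # channel lines: label,reference,resolution,unit
  ch_order <- order(as.integer(sub("^Ch", "", names(hd$channels))))
  ch <- hd$channels[ch_order]
  fields <- lapply(ch, function(v) strsplit(v, ",", fixed = TRUE)[[1]])
  labels <- vapply(fields, `[`, "", 1)
  res <- vapply(fields, function(f) {
    r <- suppressWarnings(as.numeric(f[3]))
    if (is.na(r) || length(f) < 3 || f[3] == "") 1 else r
  }, 0)
  unit <- vapply(fields, function(f) if (length(f) >= 4) f[4] else "", "")
  sz <- file.size(data_file)
  if (binfmt == "IEEE_FLOAT_32") {
    nval <- sz %/% 4L
    raw <- readBin(data_file, "numeric", n = nval, size = 4, endian = "little")
  } else if (binfmt == "INT_16") {
    nval <- sz %/% 2L
    raw <- readBin(data_file, "integer", n = nval, size = 2, signed = TRUE,
                   endian = "little")
  } else stopf("read_recording: BinaryFormat '%s' unsupported", binfmt)
  nsamp <- length(raw) %/% nch
  raw <- raw[seq_len(nsamp * nch)]
  X <- if (orient == "MULTIPLEXED") matrix(raw, nrow = nch) else
    t(matrix(raw, ncol = nch))
  X <- X * res  # counts -> physical unit
  list(samples = X, sfreq = sfreq, labels = labels, unit = unit,
       binfmt = binfmt, resolution = res)
}

unit_to_uv <- function(unit) {
  u <- trimws(unit)
  u[u %in% c("µV", "μV", "uV", "microV", "microvolt")] <- "uV"
  scale <- ifelse(u == "uV", 1, ifelse(u == "mV", 1e3, ifelse(u == "V", 1e6, NA_real_)))
  scale
}

write_brainvision <- function(samples, sfreq, labels, base_path,
                              binfmt = "IEEE_FLOAT_32", events = NULL,
                              unit = "uV") {
  nch <- nrow(samples)
  vhdr <- paste0(base_path, ".vhdr")
  vmrk <- paste0(base_path, ".vmrk")
  eeg <- paste0(base_path, ".eeg")
  res <- rep(1, nch)
  if (binfmt == "INT_16") {
    # per-channel resolution so the int16 range covers the signal
    res <- apply(abs(samples), 1, max) / 32000
    res[res == 0] <- 1e-6
  }
  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "[Common Infos]",
           paste0("DataFile=", basename(eeg)),
           paste0("MarkerFile=", basename(vmrk)),
           "DataFormat=BINARY",
           "DataOrientation=MULTIPLEXED",
           paste0("NumberOfChannels=", nch),
           paste0("SamplingInterval=", format(1e6 / sfreq, digits = 15)),
           "[Binary Infos]",
           paste0("BinaryFormat=", binfmt),
           "[Channel Infos]",
           sprintf("Ch%d=%s,,%s,%s", seq_len(nch), labels,
                   format(res, digits = 15, scientific = FALSE, trim = TRUE), unit))
  writeLines(hdr, vhdr)
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Common Infos]",
          paste0("DataFile=", basename(eeg)),
          "[Marker Infos]",
          "Mk1=New Segment,,1,1,0,0")
  if (!is.null(events) && nrow(events)) {
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,%d,0",
                        seq_len(nrow(events)) + 1L, events$code,
                        as.integer(round(events$onset * sfreq)) + 1L,
                        pmax(1L, as.integer(round(events$duration * sfreq)))))
  }
  writeLines(mk, vmrk)
  con <- file(eeg, "wb")
  on.exit(close(con))
  if (binfmt == "IEEE_FLOAT_32") {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  } else {
    counts <- as.integer(pmin(32767, pmax(-32768, round(samples / res))))
    writeBin(counts, con, size = 2, endian = "little")
  }
  invisible(c(vhdr, vmrk, eeg))
}

# --- BIDS sidecar tables ----------------------------------------------------

na_chr <- function(x) ifelse(is.na(x) | x == "", "n/a", as.character(x))

write_tsv <- function(df, path) {
  df[] <- lapply(df, function(col) {
    if (is.numeric(col)) format(col, digits = 15, trim = TRUE) else na_chr(col)
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "n/a",
                    check.names = FALSE)
}

#' Read a recording from a dataset manifest entry
#'
#' Loads the data file, checks it against the BIDS channels sidecar (order
#' and count must agree), converts samples to microvolts using the sidecar
#' unit (falling back to the data-file header), and attaches events and an
#' electrode montage when their sidecars are present.
#'
#' @param entry one row of a [scan_dataset()] manifest.
#' @return an `eeg_recording`; the source file paths are kept in
#'   `rec$source` so that derivative writing can copy raw bytes verbatim.
#' @export
read_recording <- function(entry) {
  entry <- as.list(entry)
  if (!file.exists(entry$path)) stopf("read_recording: '%s' not found", entry$path)
  if (entry$format != "brainvision")
    stopf("read_recording: format '%s' is not supported (supported: brainvision); %s",
          entry$format, "convert at the acquisition site before staging")
  bv <- read_brainvision(entry$path)
  base <- bids_base(entry)
  ch_tsv <- paste0(base, "_channels.tsv")
  unit <- bv$unit
  labels <- bv$labels
  if (file.exists(ch_tsv)) {
    cht <- read_tsv(ch_tsv)
    if (nrow(cht) != nrow(bv$samples))
      stopf("read_recording: channels sidecar lists %d channels but data holds %d",
            nrow(cht), nrow(bv$samples))
    if (!setequal(cht$name, labels))
      stopf("read_recording: channel names differ between sidecar and data file")
    ord <- match(cht$name, labels)
    bv$samples <- bv$samples[ord, , drop = FALSE]
    labels <- cht$name
    if (!is.null(cht$units)) unit <- cht$units else unit <- unit[ord]
  }
  scale <- unit_to_uv(unit)
  if (anyNA(scale))
    stopf("read_recording: channel unit missing or unrecognized (%s)",
          paste(unique(unit[is.na(scale)]), collapse = ", "))
  X <- bv$samples * scale
  ev_tsv <- paste0(base, "_events.tsv")
  ev <- event_table()
  if (file.exists(ev_tsv)) {
    et <- read_tsv(ev_tsv)
    code <- et$trial_type %||% et$value %||% rep("event", nrow(et))
    ev <- event_table(onset = et$onset, duration = et$duration,
                      code = as.character(code), hed = et$HED)
  }
  el_tsv <- paste0(base, "_electrodes.tsv")
  montage <- if (file.exists(el_tsv)) {
    et <- read_tsv(el_tsv)
    names(et)[names(et) == "name"] <- "label"
    fid_rows <- et$label %in% c("nasion", "lpa", "rpa")
    fid <- if (any(fid_rows)) {
      f <- as.matrix(et[fid_rows, c("x", "y", "z")]); rownames(f) <- et$label[fid_rows]; f
    } else NULL
    new_montage(et$label[!fid_rows],
                as.matrix(et[!fid_rows, c("x", "y", "z")]), fid)
  } else NULL
  rec <- new_recording(X, bv$sfreq, labels, events = ev, montage = montage,
                       provenance = sprintf("read_recording(%s)", basename(entry$path)))
  rec$source <- list(files = bids_source_files(entry), entry = entry)
  rec
}

bids_source_files <- function(entry) {
  base <- bids_base(entry)
  cand <- c(entry$path,
            sub("\\.vhdr$", ".vmrk", entry$path),
            sub("\\.vhdr$", ".eeg", entry$path),
            paste0(base, c("_channels.tsv", "_events.tsv", "_electrodes.tsv",
                           "_eeg.json")))
  unique(cand[file.exists(cand)])
}

#' Write a lossless derivative for one recording
#'
#' Copies the raw source files byte-identically into
#' `derivatives/<pipeline>/sub-<id>/eeg/` and emits all pipeline decisions as
#' editable sidecars: time flags as an annotations table, channel flags
#' folded into the channels table's status columns, IC flags in a dedicated
#' table, and the review state in a JSON sidecar. Re-reading with
#' [read_annotations()] reconstructs an equal annotation set.
#'
#' @param rec recording returned by [read_recording()] (its `source` field
#'   locates the raw files) or any recording (then a fresh BrainVision copy
#'   is written).
#' @param ann the [annotations()] to serialize.
#' @param out_root dataset root under which `derivatives/` is created.
#' @param pipeline derivative pipeline name (default `"lossless"`).
#' @param overwrite overwrite an existing derivative for this recording.
#' @param extra named list merged into the JSON sidecar (e.g. serialized
#'   pipeline config).
#' @return invisibly, the derivative base path (no extension).
#' @export
write_derivative <- function(rec, ann, out_root, pipeline = "lossless",
                             overwrite = FALSE, extra = list()) {
  validate_annotations(ann, rec)
  pipe_root <- file.path(out_root, "derivatives", pipeline)
  dd <- file.path(pipe_root, "dataset_description.json")
  if (!file.exists(dd)) {
    dir.create(pipe_root, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(
      Name = paste0(pipeline, " EEG quality annotations"),
      BIDSVersion = "1.8.0",
      DatasetType = "derivative",
      GeneratedBy = list(list(Name = "losslessr",
                              Version = as.character(utils::packageVersion("losslessr"))))),
      dd, auto_unbox = TRUE, pretty = TRUE)
  }
  if (!is.null(rec$source)) {
    ent <- rec$source$entry
    rel_dir <- if (is.na(ent$session %||% NA)) file.path(paste0("sub-", ent$subject), "eeg")
      else file.path(paste0("sub-", ent$subject), paste0("ses-", ent$session), "eeg")
    out_dir <- file.path(pipe_root, rel_dir)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    base <- file.path(out_dir, sub("_eeg\\.[A-Za-z]+$", "", basename(ent$path)))
    if (file.exists(paste0(base, "_desc-annotations.tsv")) && !overwrite)
      stopf("write_derivative: derivative for '%s' exists (use overwrite)", basename(ent$path))
    for (f in rec$source$files) {
      dst <- file.path(out_dir, basename(f))
      if (!file.exists(dst) || overwrite) file.copy(f, dst, overwrite = TRUE)
    }
    ch_src <- paste0(bids_base(ent), "_channels.tsv")
    cht <- if (file.exists(ch_src)) read_tsv(ch_src) else
      data.frame(name = rec$labels, type = "EEG", units = "uV",
                 stringsAsFactors = FALSE)
  } else {
    out_dir <- file.path(pipe_root, "sub-unknown", "eeg")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    base <- file.path(out_dir, "sub-unknown_task-unknown")
    if (file.exists(paste0(base, "_desc-annotations.tsv")) && !overwrite)
      stopf("write_derivative: derivative exists (use overwrite)")
    write_brainvision(rec$samples, rec$sfreq, rec$labels,
                      paste0(base, "_eeg"), events = rec$events)
    cht <- data.frame(name = rec$labels, type = "EEG", units = "uV",
                      stringsAsFactors = FALSE)
  }
  # channel flags -> status columns of the channels table
  flags <- vapply(cht$name, function(lb)
    paste(ann$channel_flags[[lb]], collapse = ","), "")
  cht$status <- ifelse(flags == "", "good", "bad")
  cht$status_description <- ifelse(flags == "", NA_character_, flags)
  write_tsv(cht, paste0(base, "_channels.tsv"))
  tf <- ann$time_flags[order(ann$time_flags$onset, ann$time_flags$label), , drop = FALSE]
  write_tsv(tf, paste0(base, "_desc-annotations.tsv"))
  ics <- if (length(ann$ic_flags))
    data.frame(component = as.integer(names(ann$ic_flags)),
               labels = vapply(ann$ic_flags, paste, "", collapse = ","),
               stringsAsFactors = FALSE)
    else data.frame(component = integer(0), labels = character(0))
  ics <- ics[order(ics$component), , drop = FALSE]
  write_tsv(ics, paste0(base, "_desc-icflags.tsv"))
  meta <- c(list(review_state = ann$review_state,
                 provenance = as.list(rec$provenance)), extra)
  jsonlite::write_json(meta, paste0(base, "_desc-lossless.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(base)
}

#' Read annotations back from a derivative
#'
#' Inverse of [write_derivative()]: reconstructs the annotation set from the
#' sidecar tables at a derivative base path.
#'
#' @param base derivative base path as returned by [write_derivative()]
#'   (path without the `_desc-*`/`_channels` suffix).
#' @return an [annotations()] object.
#' @export
read_annotations <- function(base) {
  cht <- read_tsv(paste0(base, "_channels.tsv"))
  cf <- list()
  bad <- which(!is.na(cht$status_description) & cht$status_description != "")
  for (i in bad)
    cf[[cht$name[i]]] <- sort(strsplit(cht$status_description[i], ",", fixed = TRUE)[[1]])
  tf <- read_tsv(paste0(base, "_desc-annotations.tsv"))
  tf <- if (nrow(tf)) make_intervals(tf$onset, tf$duration, tf$label) else empty_intervals()
  ict <- read_tsv(paste0(base, "_desc-icflags.tsv"))
  icf <- list()
  if (nrow(ict))
    for (i in seq_len(nrow(ict)))
      icf[[as.character(ict$component[i])]] <-
        sort(strsplit(ict$labels[i], ",", fixed = TRUE)[[1]])
  meta <- jsonlite::read_json(paste0(base, "_desc-lossless.json"))
  annotations(channel_flags = cf, time_flags = tf, ic_flags = icf,
              review_state = meta$review_state %||% "unreviewed")
}

#' Write a synthetic BIDS fixture tree
#'
#' Serializes a list of [simulate_recording()] results as a valid BIDS-EEG
#' dataset (BrainVision data files plus channels/electrodes/events sidecars)
#' with the ground truth stored under a clearly non-BIDS `truth/` subtree.
#'
#' @param sims list of `simulate_recording()` outputs.
#' @param root target directory.
#' @param tasks optional character vector of task labels (default `task` for
#'   recordings with events, `rest` otherwise).
#' @param overwrite allow writing into a non-empty root.
#' @param binfmt BrainVision binary sample format.
#' @return invisibly, the manifest-equivalent listing of written data files.
#' @export
write_bids_fixture <- function(sims, root, tasks = NULL, overwrite = FALSE,
                               binfmt = "IEEE_FLOAT_32") {
  if (dir.exists(root) && length(list.files(root)) && !overwrite)
    stopf("write_bids_fixture: '%s' is not empty (use overwrite)", root)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(Name = "synthetic lossless fixture",
                            BIDSVersion = "1.8.0", DatasetType = "raw"),
                       file.path(root, "dataset_description.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  written <- character(0)
  for (i in seq_along(sims)) {
    sim <- sims[[i]]
    rec <- sim$recording
    task <- if (!is.null(tasks)) tasks[i] else
      if (nrow(rec$events)) "task" else "rest"
    sub <- sprintf("%03d", i)
    eeg_dir <- file.path(root, paste0("sub-", sub), "eeg")
    dir.create(eeg_dir, recursive = TRUE, showWarnings = FALSE)
    base <- file.path(eeg_dir, sprintf("sub-%s_task-%s", sub, task))
    write_brainvision(rec$samples, rec$sfreq, rec$labels, paste0(base, "_eeg"),
                      binfmt = binfmt, events = rec$events)
    write_tsv(data.frame(name = rec$labels, type = "EEG", units = "uV"),
              paste0(base, "_channels.tsv"))
    m <- sim$montage
    el <- data.frame(name = m$labels, x = m$positions[, 1],
                     y = m$positions[, 2], z = m$positions[, 3])
    if (!is.null(m$fiducials))
      el <- rbind(el, data.frame(name = rownames(m$fiducials),
                                 x = m$fiducials[, 1], y = m$fiducials[, 2],
                                 z = m$fiducials[, 3]))
    write_tsv(el, paste0(base, "_electrodes.tsv"))
    if (nrow(rec$events)) {
      ev <- rec$events
      write_tsv(data.frame(onset = ev$onset, duration = ev$duration,
                           trial_type = ev$code, HED = ev$hed),
                paste0(base, "_events.tsv"))
    }
    truth_dir <- file.path(root, "truth", paste0("sub-", sub))
    dir.create(truth_dir, recursive = TRUE, showWarnings = FALSE)
    write_truth(sim$truth, truth_dir)
    written <- c(written, paste0(base, "_eeg.vhdr"))
  }
  invisible(written)
}

write_truth <- function(truth, dir) {
  ch <- if (length(truth$channels))
    data.frame(channel = names(truth$channels),
               labels = vapply(truth$channels, paste, "", collapse = ","),
               stringsAsFactors = FALSE)
    else data.frame(channel = character(0), labels = character(0))
  write_tsv(ch, file.path(dir, "truth_channels.tsv"))
  write_tsv(truth$time, file.path(dir, "truth_time.tsv"))
  jsonlite::write_json(list(source_variance = truth$source_variance,
                            seed = truth$config$seed),
                       file.path(dir, "truth_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a ground-truth sidecar written by [write_bids_fixture()]
#' @param dir per-subject truth directory.
#' @return list with `channels` (named list of labels) and `time` intervals.
#' @export
read_truth <- function(dir) {
  ch <- read_tsv(file.path(dir, "truth_channels.tsv"))
  channels <- list()
  if (nrow(ch))
    for (i in seq_len(nrow(ch)))
      channels[[ch$channel[i]]] <- strsplit(ch$labels[i], ",", fixed = TRUE)[[1]]
  tt <- read_tsv(file.path(dir, "truth_time.tsv"))
  time <- if (nrow(tt)) make_intervals(tt$onset, tt$duration, tt$label)
    else empty_intervals()
  list(channels = channels, time = time)
}
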