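pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  sprintf(sprintf("%%-%ds", width), s)
}

#' Write a continuous multichannel recording as EDF
#'
#' Minimal European Data Format writer (16-bit integer samples, one data
#' record per second). Physical scaling is chosen per channel from the data
#' range, so the round trip through [read_edf()] is exact to the 16-bit
#' quantization. Mainly used to build synthetic test recordings.
#'
#' @param data Channels x samples numeric matrix (physical units, e.g. uV).
#' @param fs Sampling rate in Hz (samples per record).
#' @param channel_labels Channel names.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(data, fs, channel_labels, path) {
  data <- as.matrix(data)
  ns <- nrow(data)
  stopifnot(length(channel_labels) == ns)
  spr <- as.integer(fs)
  n_rec <- ncol(data) %/% spr
  if (n_rec * spr != ncol(data))
    stop_invalid("sample count %d is not a whole number of 1 s records at fs = %g",
                 ncol(data), fs)
  pmin_ <- apply(data, 1, min); pmax_ <- apply(data, 1, max)
  flat <- pmax_ - pmin_ == 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("synthetic", 80), pad_field("synthetic", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field("1", 8), pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  sig_fields <- c(
    vapply(channel_labels, pad_field, "", width = 16),
    rep(pad_field("", 80), ns),
    rep(pad_field("uV", 8), ns),
    vapply(pmin_, function(v) pad_field(formatC(v, digits = 7, format = "g"), 8), ""),
    vapply(pmax_, function(v) pad_field(formatC(v, digits = 7, format = "g"), 8), ""),
    rep(pad_field(dmin, 8), ns),
    rep(pad_field(dmax, 8), ns),
    rep(pad_field("", 80), ns),
    rep(pad_field(spr, 8), ns),
    rep(pad_field("", 32), ns))
  writeChar(paste0(sig_fields, collapse = ""), con, eos = NULL)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- (r - 1L) * spr + seq_len(spr)
    for (ch in seq_len(ns)) {
      dig <- round((data[ch, idx] - pmin_[ch]) / scale[ch]) + dmin
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Parses the EDF header and 16-bit data records, applying each channel's
#' physical scaling. All channels must share one sampling rate.
#'
#' @param path EDF file.
#' @return List with `data` (channels x samples, physical units),
#'   `channel_labels`, `fs`, `n_records`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop_invalid("malformed EDF header (version field '%s')", version)
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop_invalid("malformed EDF header (signal count)")
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16); fld(80); fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  if (length(unique(spr)) != 1)
    stop_invalid("channels with heterogeneous sampling rates are not supported")
  if (header_bytes != 256 * (1 + ns))
    stop_invalid("malformed EDF header (header byte count)")
  fs <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      data[ch, (r - 1L) * spr[1] + seq_len(spr[1])] <-
        (dig - dmin[ch]) * scale[ch] + pmin_[ch]
    }
  }
  list(data = data, channel_labels = labels, fs = fs, n_records = n_rec)
}

#' Write an epoch/array bundle to the pipeline container
#'
#' The container is a JSON sidecar (`<path>.json`, dimensions and metadata)
#' plus raw little-endian doubles (`<path>.bin`), so the round trip is
#' exactly lossless.
#'
#' @param bundle A `sensor_epochs`, `roi_series`, or plain numeric array.
#' @param path Path stem (extensions are appended).
#' @return `path`, invisibly.
#' @export
write_container <- function(bundle, path) {
  if (inherits(bundle, "sensor_epochs")) {
    meta <- list(type = "sensor_epochs", dim = dim(bundle$data),
                 channel_labels = bundle$channel_labels, fs = bundle$fs,
                 window = bundle$window, interval_tag = bundle$interval_tag,
                 task_id = bundle$task_id, categories = bundle$categories,
                 bad_channels = bundle$bad_channels)
    payload <- bundle$data
  } else if (inherits(bundle, "roi_series")) {
    meta <- list(type = "roi_series", dim = dim(bundle$series),
                 roi_labels = bundle$roi_labels, fs = bundle$fs,
                 interval_tag = bundle$interval_tag)
    payload <- bundle$series
  } else {
    payload <- as.array(bundle)
    meta <- list(type = "array", dim = dim(payload), fs = attr(bundle, "fs"))
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(payload), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a container written by [write_container()]
#' @param path Path stem used at write time.
#' @return The reconstructed object.
#' @export
read_container <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  payload <- array(readBin(con, "numeric", n, size = 8, endian = "little"),
                   dim = meta$dim)
  switch(meta$type,
    sensor_epochs = {
      cats <- meta$categories
      if (is.null(cats)) cats <- rep(list(character(0)), meta$dim[1])
      if (!is.list(cats)) cats <- as.list(cats)
      cats <- lapply(cats, function(x) if (is.null(x)) character(0) else unlist(x))
      sensor_epochs(payload, meta$channel_labels, meta$fs,
                    window = meta$window, interval_tag = meta$interval_tag,
                    task_id = meta$task_id, categories = cats,
                    bad_channels = meta$bad_channels %||% character(0))
    },
    roi_series = structure(
      list(series = matrix(payload, meta$dim[1], meta$dim[2],
                           dimnames = list(meta$roi_labels, NULL)),
           roi_labels = meta$roi_labels, fs = meta$fs,
           interval_tag = meta$interval_tag),
      class = "roi_series"),
    array = {
      if (!is.null(meta$fs)) attr(payload, "fs") <- meta$fs
      payload
    },
    stop_invalid("unknown container type '%s'", meta$type))
}

#' Write a lead field as delimited text plus a JSON ROI map
#'
#' Tab-separated matrix with a sensor-label first column and dipole-index
#' header; the ROI membership map goes to `<path>.rois.json` as
#' `{roi_label: [0-based dipole indices]}`.
#'
#' @param lf A `lead_field`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_lead_field <- function(lf, path) {
  stopifnot(inherits(lf, "lead_field"))
  df <- data.frame(sensor = lf$sensor_labels,
                   formatC(lf$matrix, format = "g", digits = 17))
  names(df)[-1] <- sprintf("d%04d", seq_len(ncol(lf$matrix)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rois <- unique(lf$dipole_roi)
  roi_map <- stats::setNames(
    lapply(rois, function(r) which(lf$dipole_roi == r) - 1L), rois)
  jsonlite::write_json(roi_map, paste0(path, ".rois.json"))
  invisible(path)
}

#' Read a lead field written by [write_lead_field()]
#' @param path TSV path (expects `<path>.rois.json` alongside).
#' @return A `lead_field`.
#' @export
read_lead_field <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sensor" %in% names(df))
    stop_invalid("lead-field file lacks the sensor-label column")
  mat <- as.matrix(df[, -1, drop = FALSE])
  roi_map <- jsonlite::read_json(paste0(path, ".rois.json"),
                                 simplifyVector = TRUE)
  dipole_roi <- character(ncol(mat))
  for (r in names(roi_map)) dipole_roi[unlist(roi_map[[r]]) + 1L] <- r
  if (any(dipole_roi == ""))
    stop_invalid("ROI map does not cover every dipole")
  lead_field(mat, df$sensor, dipole_roi)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a directed network as GraphML
#'
#' Edges carry `weight` and `significant` attributes; only nonzero edges
#' (or, for thresholded networks, edges surviving the mask or with nonzero
#' raw weight) are emitted.
#'
#' @param adj `connectivity_matrix` or square weighted adjacency
#'   (row = target, column = source).
#' @param path Output file.
#' @param node_labels Node names (default from dimnames or N1..Nk).
#' @return `path`, invisibly.
#' @export
write_graphml <- function(adj, path, node_labels = NULL) {
  sig <- NULL
  if (inherits(adj, "connectivity_matrix")) {
    sig <- adj$sig_mask
    adj <- adj$weights
  }
  adj <- as.matrix(adj)
  k <- nrow(adj)
  if (is.null(node_labels))
    node_labels <- rownames(adj) %||% sprintf("N%d", seq_len(k))
  if (is.null(sig)) sig <- adj != 0
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="weight" for="edge" attr.name="weight" attr.type="double"/>',
    '  <key id="significant" for="edge" attr.name="significant" attr.type="boolean"/>',
    '  <graph id="G" edgedefault="directed">',
    sprintf('    <node id="%s"/>', xml_escape(node_labels)))
  for (src in seq_len(k)) for (tgt in seq_len(k)) {
    if (src == tgt || adj[tgt, src] == 0) next
    lines <- c(lines, sprintf(
      '    <edge source="%s" target="%s"><data key="weight">%.17g</data><data key="significant">%s</data></edge>',
      xml_escape(node_labels[src]), xml_escape(node_labels[tgt]),
      adj[tgt, src], tolower(sig[tgt, src])))
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  writeLines(lines, path)
  invisible(path)
}

#' Write a network as an edge-list CSV
#'
#' Columns `source,target,weight` (and `significant` for thresholded
#' networks); the explicit source/target labelling avoids transposition
#' ambiguity of the internal row = target storage.
#'
#' @inheritParams write_graphml
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(adj, path, node_labels = NULL) {
  sig <- NULL
  if (inherits(adj, "connectivity_matrix")) {
    sig <- adj$sig_mask
    adj <- adj$weights
  }
  adj <- as.matrix(adj)
  k <- nrow(adj)
  if (is.null(node_labels))
    node_labels <- rownames(adj) %||% sprintf("N%d", seq_len(k))
  idx <- which(adj != 0 & row(adj) != col(adj), arr.ind = TRUE)
  df <- data.frame(source = node_labels[idx[, 2]],
                   target = node_labels[idx[, 1]],
                   weight = adj[idx])
  if (!is.null(sig)) df$significant <- sig[idx]
  df <- df[order(df$source, df$target), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an experiment schedule as CSV (with categories) or JSON
#'
#' @param schedule An `experiment_schedule`.
#' @param path Output file; format chosen by extension (.csv or .json).
#' @param categories Optional named list task_id -> category vector; when
#'   omitted, ids matching the built-in taxonomy are annotated.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path, categories = NULL) {
  df <- as.data.frame(schedule)
  cat_of <- function(id) {
    if (!is.null(categories)) return(paste(categories[[id]], collapse = ";"))
    tryCatch(paste(task_categories(id), collapse = ";"),
             error = function(e) "")
  }
  df$categories <- vapply(df$task_id, cat_of, "")
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(n_repetitions = attr(schedule, "n_repetitions"),
           video_s = attr(schedule, "video_s"),
           rest_s = attr(schedule, "rest_s"),
           presentations = df),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a schedule written by [write_schedule()]
#' @param path CSV or JSON schedule file.
#' @return An `experiment_schedule` data frame.
#' @export
read_schedule <- function(path) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- obj$presentations
    structure(df[, c("task_id", "part", "onset_s")],
              class = c("experiment_schedule", "data.frame"),
              n_repetitions = obj$n_repetitions,
              video_s = obj$video_s, rest_s = obj$rest_s)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    structure(df[, c("task_id", "part", "onset_s")],
              class = c("experiment_schedule", "data.frame"))
  }
}
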