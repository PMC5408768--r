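#' Read / write an event table
#'
#' Portable plain-text event format: tab-separated with header columns
#' `start`, `length`, `mean`, `stdv` (seconds / seconds / pA / pA) and an
#' optional leading `#read_id=...` comment line. The read id defaults to
#' the file stem. Start times must be nondecreasing and lengths positive.
#'
#' @param path file path.
#' @return list of class `read_record`: `read_id`, `events` data.frame,
#'   `source`.
#' @export
read_event_table <- function(path) {
  lines <- readLines(path)
  read_id <- sub("\\.[^.]*$", "", basename(path))
  skip <- 0L
  if (length(lines) && startsWith(lines[1], "#")) {
    if (grepl("^#read_id=", lines[1]))
      read_id <- sub("^#read_id=", "", lines[1])
    skip <- 1L
  }
  tab <- tryCatch(
    read.table(text = lines, header = TRUE, sep = "\t", skip = skip),
    error = function(e) stop("cannot parse event table ", path, ": ",
                             conditionMessage(e)))
  for (col in c("start", "length", "mean", "stdv")) {
    if (!col %in% names(tab))
      stop("event table ", path, " missing column \"", col, "\"")
    if (!is.numeric(tab[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[col]]))))[1]
      stop("non-numeric value in column \"", col, "\" at data line ",
           bad, " of ", path)
    }
  }
  if (nrow(tab) == 0L) stop("event table ", path, " has no events")
  if (any(tab$length <= 0)) {
    stop("non-positive event length at data line ",
         which(tab$length <= 0)[1], " of ", path)
  }
  if (is.unsorted(tab$start))
    stop("event start times are not nondecreasing in ", path)
  structure(list(read_id = read_id,
                 events = tab[c("start", "length", "mean", "stdv")],
                 source = path),
            class = "read_record")
}

#' @rdname read_event_table
#' @param events event data.frame.
#' @param read_id read identifier stored in the header comment.
#' @export
write_event_table <- function(events, path, read_id = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(read_id)) writeLines(paste0("#read_id=", read_id), con)
  writeLines("start\tlength\tmean\tstdv", con)
  writeLines(sprintf("%.17g\t%.17g\t%.17g\t%.17g", events$start,
                     events$length, events$mean, events$stdv), con)
  invisible(path)
}

#' Read events from a FAST5 (HDF5) file
#'
#' Pre-basecalled FAST5 files store an EventDetection-style events table
#' whose group path varies between instrument software versions; a list of
#' candidate paths is searched and the first match used. Start and length
#' are converted from raw sample counts to seconds using the channel
#' sampling rate when present. R has no HDF5 bindings in this toolchain,
#' so the extraction is delegated to a bundled Python helper (requires
#' `python` with `h5py` on the PATH).
#'
#' @param path FAST5 file path.
#' @return a `read_record` as in [read_event_table()].
#' @export
read_fast5_events <- function(path) {
  helper <- system.file("python", "fast5_events.py", package = "porecall")
  if (helper == "") stop("bundled FAST5 helper not found")
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  status <- suppressWarnings(
    system2("python", c(helper, shQuote(path), shQuote(tmp)),
            stdout = TRUE, stderr = TRUE))
  code <- attr(status, "status")
  if (!is.null(code) && code != 0)
    stop("FAST5 read failed for ", path, ": ",
         paste(status, collapse = " "))
  rec <- read_event_table(tmp)
  rec$source <- path
  rec$read_id <- sub("\\.[^.]*$", "", basename(path))
  if (length(status) && any(grepl("^#read_id=", status)))
    rec$read_id <- sub("^#read_id=", "",
                       grep("^#read_id=", status, value = TRUE)[1])
  rec
}

#' Write / read a simulation truth record
#'
#' Sidecar TSV holding the ground truth of a simulated read: sequences,
#' island coordinates and the true generative parameters, as key-value
#' rows. Write then read round-trips all values.
#'
#' @param truth the `truth` element of a [simulate_read()] result.
#' @param path file path.
#' @param read_id read identifier.
#' @export
write_truth_record <- function(truth, path, read_id = "read") {
  s <- truth$scaling
  kv <- c(read_id = read_id,
          template_seq = truth$template_seq,
          complement_seq = truth$complement_seq,
          island_start = if (is.null(truth$island)) "NA"
                         else truth$island[1],
          island_end = if (is.null(truth$island)) "NA"
                       else truth$island[2],
          p_stay = sprintf("%.17g", truth$p_stay),
          p_skip = sprintf("%.17g", truth$p_skip),
          shift = sprintf("%.17g", s$shift),
          scale = sprintf("%.17g", s$scale),
          drift = sprintf("%.17g", s$drift),
          var = sprintf("%.17g", s$var),
          scale_sd = sprintf("%.17g", s$scale_sd),
          var_sd = sprintf("%.17g", s$var_sd))
  writeLines(c("key\tvalue", paste(names(kv), kv, sep = "\t")), path)
  invisible(path)
}

#' @rdname write_truth_record
#' @export
read_truth_record <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character")
  kv <- setNames(tab$value, tab$key)
  num <- function(x) as.numeric(kv[[x]])
  island <- if (kv[["island_start"]] == "NA") NULL
            else c(as.integer(kv[["island_start"]]),
                   as.integer(kv[["island_end"]]))
  list(read_id = kv[["read_id"]],
       template_seq = kv[["template_seq"]],
       complement_seq = kv[["complement_seq"]],
       island = island, p_stay = num("p_stay"), p_skip = num("p_skip"),
       scaling = scaling_params(shift = num("shift"), scale = num("scale"),
                                drift = num("drift"), var = num("var"),
                                scale_sd = num("scale_sd"),
                                var_sd = num("var_sd")))
}
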