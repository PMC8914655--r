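#' Motion-trace file I/O
#'
#' Traces are stored as JSON lines: one header object on the first line,
#' then one frame object per line.  The dialect mirrors what a skeletal
#' tracking API exposes per frame — per-bone begin/end positions in mm and
#' orientation quaternions, plus the wrist pose and hand side:
#'
#' ```
#' {"schema_version":"1.0","units":{"position":"mm","angle":"deg"},
#'  "capture_rate":60,"device_label":"..."}
#' {"timestamp_us":0,"side":"right",
#'  "wrist":{"position_mm":[x,y,z],"quaternion":[w,x,y,z]},
#'  "fingers":{"thumb":{"bones":[
#'     {"bone":"metacarpal","begin_mm":[...],"end_mm":[...],
#'      "quaternion":[...]}, ...]}, ...}}
#' ```
#'
#' Bone records are ordered metacarpal, proximal, intermediate, distal.
#' Each bone's frame sits at its begin point with the stored orientation;
#' the tip frame sits at the distal bone's end point with the distal
#' orientation.  Recording both begin and end per bone is redundant
#' (consecutive bones share a joint point) but self-checking.
#' Serialization is canonical — fixed field order, full floating-point
#' precision — so equal traces produce identical bytes.  A machine-readable
#' schema ships in `inst/extdata/trace-schema.json`.
#'
#' @name frame_io
NULL

TRACE_SCHEMA_VERSION <- "1.0"

BONE_ORDER <- c("metacarpal", "proximal", "intermediate", "distal")

# ---- writing ----------------------------------------------------------------

# Raw per-frame world record: wrist pose + per-bone begin/end/quaternion.
# Generated traces and read traces carry this cache so serialization is
# byte-stable; it is derived from the graph when absent.
world_record_of <- function(sample) {
  if (!is.null(sample$world_record)) return(sample$world_record)
  g <- sample$graph
  wq <- pose_from_transform(sample$wrist_pose)
  rec <- list(wrist = list(position_mm = wq$translation,
                           quaternion = wq$quaternion),
              fingers = list())
  fingers <- intersect(HAND_FINGERS, unique(sub("_.*$", "", g$nodes)))
  for (f in fingers) {
    bones <- list()
    for (b in BONE_ORDER) {
      frame <- paste(f, b, sep = "_")
      nxt <- segment_frame(f, b)
      if (!frame %in% g$nodes || !nxt %in% g$nodes) next
      h <- compose_transforms(sample$wrist_pose, frame_in_root(g, frame))
      h_next <- compose_transforms(sample$wrist_pose, frame_in_root(g, nxt))
      p <- pose_from_transform(h)
      bones[[length(bones) + 1L]] <- list(
        bone = b,
        begin_mm = p$translation,
        end_mm = transform_translation(h_next),
        quaternion = p$quaternion
      )
    }
    rec$fingers[[f]] <- list(bones = bones)
  }
  rec
}

frame_to_json <- function(sample) {
  rec <- world_record_of(sample)
  obj <- list(timestamp_us = sample$timestamp_us,
              side = sample$side,
              wrist = rec$wrist,
              fingers = rec$fingers)
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, always_decimal = FALSE)
}

#' Write a motion trace to a JSON-lines file
#'
#' Frames are serialized and written one line at a time (constant-bounded
#' buffering).  Output is canonical: writing the result of [read_trace()]
#' reproduces the file byte for byte.
#'
#' @param trace a [motion_trace()].
#' @param path output file path or writable connection.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "motion_trace"))
  con <- if (inherits(path, "connection")) path else {
    f <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write trace to '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
    on.exit(close(f))
    f
  }
  header <- jsonlite::toJSON(
    list(schema_version = TRACE_SCHEMA_VERSION,
         units = list(position = "mm", angle = "deg"),
         capture_rate = trace$capture_rate,
         device_label = trace$device_label),
    auto_unbox = TRUE, digits = NA)
  writeLines(header, con, useBytes = TRUE)
  for (s in trace$samples) {
    writeLines(frame_to_json(s), con, useBytes = TRUE)
  }
  invisible(path)
}

# ---- reading ----------------------------------------------------------------

parse_header <- function(line) {
  h <- tryCatch(jsonlite::fromJSON(line, simplifyVector = FALSE),
                error = function(e) stop("malformed trace header (line 1): ",
                                         conditionMessage(e), call. = FALSE))
  if (is.null(h$schema_version) ||
      !identical(h$schema_version, TRACE_SCHEMA_VERSION)) {
    stop("unsupported trace schema_version '", h$schema_version,
         "' (expected '", TRACE_SCHEMA_VERSION, "')", call. = FALSE)
  }
  if (!identical(h$units$position, "mm")) {
    stop("trace positions must be in mm, got '", h$units$position, "'",
         call. = FALSE)
  }
  h
}

parse_frame <- function(obj) {
  if (is.null(obj$timestamp_us) || is.null(obj$side)) {
    stop("frame is missing timestamp_us or side")
  }
  if (is.null(obj$wrist) || length(obj$fingers) == 0) {
    return(NULL)  # no tracked hand in this frame: skip
  }
  wq <- as.numeric(unlist(obj$wrist$quaternion))
  wp <- as.numeric(unlist(obj$wrist$position_mm))
  world <- list(wrist = transform_from_pose(wq, wp))
  rec <- list(wrist = list(position_mm = wp, quaternion = wq),
              fingers = list())
  for (f in names(obj$fingers)) {
    bones <- obj$fingers[[f]]$bones
    rec_bones <- list()
    last <- NULL
    for (i in seq_along(bones)) {
      b <- bones[[i]]
      q <- as.numeric(unlist(b$quaternion))
      begin <- as.numeric(unlist(b$begin_mm))
      end <- as.numeric(unlist(b$end_mm))
      stopifnot(length(q) == 4L, length(begin) == 3L, length(end) == 3L)
      frame <- paste(f, b$bone, sep = "_")
      world[[frame]] <- transform_from_pose(q, begin)
      rec_bones[[i]] <- list(bone = b$bone, begin_mm = begin,
                             end_mm = end, quaternion = q)
      last <- rec_bones[[i]]
    }
    if (!is.null(last) && identical(last$bone, "distal")) {
      world[[paste(f, "tip", sep = "_")]] <-
        transform_from_pose(last$quaternion, last$end_mm)
    }
    rec$fingers[[f]] <- list(bones = rec_bones)
  }
  sk <- skeleton_from_world_poses(world)
  s <- hand_frame_sample(obj$timestamp_us, obj$side, sk$wrist_pose, sk$graph)
  s$world_record <- rec
  s
}

#' Read a motion trace from a JSON-lines file
#'
#' @param path input file path or readable connection.
#' @param strict if `TRUE` (default), any malformed frame line aborts with
#'   an error naming the line; if `FALSE`, malformed lines are skipped and
#'   counted.  Measurement software should fail loudly, hence the strict
#'   default.
#' @return a [motion_trace()] with attributes `n_skipped` (frames without a
#'   tracked hand) and `n_malformed` (lenient mode only).
#' @export
read_trace <- function(path, strict = TRUE) {
  con <- if (inherits(path, "connection")) path else {
    f <- tryCatch(file(path, open = "rt"),
                  error = function(e) stop("cannot read trace from '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
    on.exit(close(f))
    f
  }
  header_line <- readLines(con, n = 1L)
  if (length(header_line) == 0) {
    stop("empty trace file: missing header line", call. = FALSE)
  }
  header <- parse_header(header_line)
  samples <- list()
  n_skipped <- 0L
  n_malformed <- 0L
  last_ts <- -Inf
  line_no <- 1L
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0) break
    line_no <- line_no + 1L
    if (!nzchar(trimws(line))) next
    s <- tryCatch({
      obj <- jsonlite::fromJSON(line, simplifyVector = FALSE)
      parse_frame(obj)
    }, error = function(e) e)
    if (inherits(s, "error")) {
      if (strict) {
        stop("malformed frame at line ", line_no, ": ",
             conditionMessage(s), call. = FALSE)
      }
      n_malformed <- n_malformed + 1L
      next
    }
    if (is.null(s)) { n_skipped <- n_skipped + 1L; next }
    if (s$timestamp_us < last_ts) {
      stop("timestamp regression at line ", line_no, " (",
           s$timestamp_us, " after ", last_ts, ")", call. = FALSE)
    }
    last_ts <- s$timestamp_us
    samples[[length(samples) + 1L]] <- s
  }
  tr <- motion_trace(samples,
                     capture_rate = header$capture_rate,
                     device_label = header$device_label)
  attr(tr, "n_skipped") <- n_skipped
  attr(tr, "n_malformed") <- n_malformed
  tr
}

# ---- results export ---------------------------------------------------------

RESULT_COLUMNS <- c("participant", "device", "hand_side", "hand_part",
                    "repetition", "value", "units")

#' Export measurement results as CSV
#'
#' Writes rows of labelled measure values in a fixed column order
#' (participant, device, hand_side, hand_part, repetition, value, units),
#' RFC-4180 style.  Every hand part must carry a single unit.
#'
#' @param rows data.frame with the columns above.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_results <- function(rows, path) {
  missing <- setdiff(RESULT_COLUMNS, names(rows))
  if (length(missing) > 0) {
    stop("results are missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  by_part <- split(rows$units, rows$hand_part)
  mixed <- names(by_part)[vapply(by_part,
                                 function(u) length(unique(u)) > 1,
                                 logical(1))]
  if (length(mixed) > 0) {
    stop("mixed units for hand part(s): ", paste(mixed, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(rows[, RESULT_COLUMNS], path, row.names = FALSE,
                   quote = which(RESULT_COLUMNS %in%
                                   c("participant", "device", "hand_side",
                                     "hand_part", "units")))
  invisible(path)
}

#' Read a results CSV written by [export_results()]
#'
#' @param path CSV path.
#' @return data.frame with the fixed result columns.
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(RESULT_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("not a results CSV; missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}
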