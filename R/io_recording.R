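# Recording file formats. The native dialect is a plain CSV (comma
# separated, header row, `time_s` column, SI units, locale-independent):
# time_s, <joint>_x, <joint>_y, <joint>_z, ... A BVH-style reader is
# provided for interoperability with motion-capture tooling; hierarchies are
# reduced to world-space positions of the mapped joints by forward
# kinematics.

CANONICAL_JOINTS <- c("left_foot", "right_foot", "pelvis")

#' Write a recording to CSV
#'
#' @param recording A `motion_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  validate_recording(recording)
  ts <- (seq_len(recording$n_samples) - 1) / recording$sampling_rate
  cols <- list(time_s = ts)
  for (j in names(recording$joints)) {
    m <- recording$joints[[j]]
    cols[[paste0(j, "_x")]] <- m[, 1]
    cols[[paste0(j, "_y")]] <- m[, 2]
    cols[[paste0(j, "_z")]] <- m[, 3]
  }
  utils::write.csv(as.data.frame(cols), path, row.names = FALSE)
  invisible(path)
}

#' Read a recording from CSV or BVH
#'
#' CSV files must carry a strictly increasing `time_s` column at 60 or
#' 120 Hz and x/y/z columns for every canonical joint; violations are parse
#' errors (with the offending line for non-monotone time), never silent
#' repairs. BVH files are parsed as a joint hierarchy, world-space positions
#' are computed by forward kinematics, and `joint_map` renames skeleton
#' joints to the canonical set.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"bvh"`.
#' @param participant_id,label,severity Metadata to attach (normally taken
#'   from a cohort manifest).
#' @param joint_map Named character vector, BVH joint name -> canonical
#'   name.
#' @param scale Multiplier applied to BVH lengths (use 0.01 for
#'   centimetre files).
#' @return A `motion_recording`.
#' @export
read_recording <- function(path, dialect = c("csv", "bvh"),
                           participant_id = "P01", label = "healthy",
                           severity = 0,
                           joint_map = c(Hips = "pelvis",
                                         LeftFoot = "left_foot",
                                         RightFoot = "right_foot"),
                           scale = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "csv") {
    read_recording_csv(path, participant_id, label, severity)
  } else {
    read_recording_bvh(path, participant_id, label, severity, joint_map,
                       scale)
  }
}

read_recording_csv <- function(path, participant_id, label, severity) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stopf("parse error: missing 'time_s' column")
  dt <- diff(df$time_s)
  if (any(dt <= 0)) {
    stopf("parse error: non-monotone time_s at line %d",
          which(dt <= 0)[1] + 2L)  # +1 header, +1 diff offset
  }
  fs <- 1 / stats::median(dt)
  fs <- c(60, 120)[which.min(abs(c(60, 120) - fs))]
  if (abs(1 / stats::median(dt) - fs) > 0.5) {
    stopf("parse error: sampling rate %.2f Hz is neither 60 nor 120",
          1 / stats::median(dt))
  }
  joint_names <- unique(sub("_[xyz]$", "",
                            grep("_[xyz]$", names(df), value = TRUE)))
  joints <- list()
  for (j in joint_names) {
    need <- paste0(j, c("_x", "_y", "_z"))
    if (!all(need %in% names(df))) {
      stopf("parse error: incomplete coordinate columns for joint '%s'", j)
    }
    joints[[j]] <- as.matrix(df[, need])
    colnames(joints[[j]]) <- c("x", "y", "z")
  }
  miss <- setdiff(CANONICAL_JOINTS, names(joints))
  if (length(miss)) {
    stopf("parse error: missing joint column(s): %s",
          paste(miss, collapse = ", "))
  }
  motion_recording(participant_id, label, severity, fs, joints)
}

# ---- BVH -------------------------------------------------------------------

read_recording_bvh <- function(path, participant_id, label, severity,
                               joint_map, scale) {
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "\\s+")
  motion_at <- which(vapply(toks, function(t) length(t) >= 1 &&
                              toupper(t[1]) == "MOTION", TRUE))[1]
  if (is.na(motion_at)) stopf("parse error: no MOTION section")
  skel <- parse_bvh_hierarchy(toks[seq_len(motion_at - 1L)])
  ft_line <- grep("^Frame Time", trimws(lines), value = TRUE)[1]
  if (is.na(ft_line)) stopf("parse error: no Frame Time line")
  frame_time <- as.numeric(sub(".*:", "", ft_line))
  fs <- round(1 / frame_time)
  data_lines <- lines[(motion_at + 3L):length(lines)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  vals <- lapply(data_lines, function(l) as.numeric(strsplit(trimws(l),
                                                             "\\s+")[[1]]))
  nch <- sum(vapply(skel$joints, function(j) length(j$channels), 0L))
  bad <- which(vapply(vals, length, 0L) != nch)
  if (length(bad)) {
    stopf("parse error: frame at line %d has %d values, expected %d",
          motion_at + 2L + bad[1], length(vals[[bad[1]]]), nch)
  }
  frames <- do.call(rbind, vals)
  world <- bvh_world_positions(skel, frames)
  joints <- list()
  for (src in names(joint_map)) {
    if (!src %in% names(world)) {
      stopf("parse error: BVH joint '%s' (mapped to %s) not found", src,
            joint_map[[src]])
    }
    joints[[joint_map[[src]]]] <- world[[src]] * scale
  }
  motion_recording(participant_id, label, severity, fs, joints)
}

parse_bvh_hierarchy <- function(toks) {
  joints <- list()
  stack <- integer(0)
  cur <- NA_integer_
  i <- 1L
  while (i <= length(toks)) {
    t <- toks[[i]]
    if (length(t) == 0L || !nzchar(t[1])) { i <- i + 1L; next }
    kw <- toupper(t[1])
    if (kw %in% c("ROOT", "JOINT")) {
      joints[[length(joints) + 1L]] <- list(
        name = t[2], parent = if (length(stack)) stack[length(stack)]
                              else NA_integer_,
        offset = c(0, 0, 0), channels = character(0))
      cur <- length(joints)
    } else if (kw == "END") {  # End Site: anonymous leaf, no channels
      joints[[length(joints) + 1L]] <- list(
        name = paste0(joints[[stack[length(stack)]]]$name, "_end"),
        parent = stack[length(stack)], offset = c(0, 0, 0),
        channels = character(0))
      cur <- length(joints)
    } else if (kw == "{") {
      stack <- c(stack, cur)
    } else if (kw == "}") {
      stack <- stack[-length(stack)]
      cur <- if (length(stack)) stack[length(stack)] else NA_integer_
    } else if (kw == "OFFSET") {
      joints[[cur]]$offset <- as.numeric(t[2:4])
    } else if (kw == "CHANNELS") {
      joints[[cur]]$channels <- t[3:(2L + as.integer(t[2]))]
    }
    i <- i + 1L
  }
  list(joints = joints)
}

rot_mat <- function(axis, deg) {
  a <- deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    X = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    Y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    Z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

# world positions of every joint for every frame (list of n x 3 matrices)
bvh_world_positions <- function(skel, frames) {
  joints <- skel$joints
  offsets <- cumsum(c(0, vapply(joints, function(j) length(j$channels),
                                0L)))[seq_along(joints)]
  n <- nrow(frames)
  out <- lapply(joints, function(j) matrix(0, n, 3))
  names(out) <- vapply(joints, `[[`, "", "name")
  rots <- vector("list", length(joints))
  for (f in seq_len(n)) {
    for (k in seq_along(joints)) {
      j <- joints[[k]]
      ch <- frames[f, offsets[k] + seq_along(j$channels)]
      pos_local <- j$offset
      rot_local <- diag(3)
      for (ci in seq_along(j$channels)) {
        cn <- tolower(j$channels[ci])
        if (cn == "xposition") pos_local[1] <- pos_local[1] + ch[ci]
        if (cn == "yposition") pos_local[2] <- pos_local[2] + ch[ci]
        if (cn == "zposition") pos_local[3] <- pos_local[3] + ch[ci]
        if (grepl("rotation", cn)) {
          rot_local <- rot_local %*% rot_mat(toupper(substr(cn, 1, 1)),
                                             ch[ci])
        }
      }
      if (is.na(j$parent)) {
        out[[k]][f, ] <- pos_local
        rots[[k]] <- rot_local
      } else {
        pr <- rots[[j$parent]]
        out[[k]][f, ] <- out[[j$parent]][f, ] + as.numeric(pr %*% pos_local)
        rots[[k]] <- pr %*% rot_local
      }
    }
  }
  lapply(out, function(m) { colnames(m) <- c("x", "y", "z"); m })
}

#' Write a recording as a BVH-style file
#'
#' Emits a flat hierarchy (pelvis root with the two feet as children) using
#' translation channels only — sufficient to round-trip positional data
#' through the BVH reader and to exchange trajectories with motion-capture
#' tools that accept position channels.
#'
#' @param recording A `motion_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording_bvh <- function(recording, path) {
  validate_recording(recording)
  pel <- recording$joints$pelvis
  lf <- recording$joints$left_foot - pel
  rf <- recording$joints$right_foot - pel
  hdr <- c(
    "HIERARCHY",
    "ROOT Hips", "{", "  OFFSET 0 0 0",
    "  CHANNELS 3 Xposition Yposition Zposition",
    "  JOINT LeftFoot", "  {", "    OFFSET 0 0 0",
    "    CHANNELS 3 Xposition Yposition Zposition",
    "    End Site", "    {", "      OFFSET 0 0 0", "    }", "  }",
    "  JOINT RightFoot", "  {", "    OFFSET 0 0 0",
    "    CHANNELS 3 Xposition Yposition Zposition",
    "    End Site", "    {", "      OFFSET 0 0 0", "    }", "  }",
    "}",
    "MOTION",
    sprintf("Frames: %d", recording$n_samples),
    sprintf("Frame Time: %.8f", 1 / recording$sampling_rate))
  dat <- cbind(pel, lf, rf)
  body <- apply(dat, 1L, function(r) paste(sprintf("%.9g", r),
                                           collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a cohort to disk
#'
#' One recording CSV per participant, a manifest CSV
#' (`participant_id,label,severity,file,sampling_rate`) and the ground truth
#' as JSON.
#'
#' @param cohort List of `list(recording, truth)` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (entry in cohort) {
    rec <- entry$recording
    file <- paste0(rec$participant_id, ".csv")
    write_recording(rec, file.path(dir, file))
    if (!is.null(entry$truth)) {
      jsonlite::write_json(
        list(contacts = entry$truth$contacts,
             turn_intervals = entry$truth$turn_intervals,
             steps = entry$truth$steps),
        file.path(dir, paste0(rec$participant_id, "_truth.json")),
        dataframe = "columns", digits = NA)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      participant_id = rec$participant_id, label = rec$label,
      severity = rec$severity, file = file,
      sampling_rate = rec$sampling_rate, stringsAsFactors = FALSE)
  }
  manifest <- file.path(dir, "cohort.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `cohort.csv` and the per-recording files.
#' @return List of `motion_recording` objects.
#' @export
read_cohort <- function(dir) {
  manifest <- file.path(dir, "cohort.csv")
  if (!file.exists(manifest)) stopf("no cohort manifest at %s", manifest)
  man <- utils::read.csv(manifest)
  lapply(seq_len(nrow(man)), function(i) {
    read_recording(file.path(dir, man$file[i]), "csv",
                   participant_id = man$participant_id[i],
                   label = man$label[i], severity = man$severity[i])
  })
}

#' Write a feature table as CSV
#'
#' Fixed column order (metadata, then the seven feature values), plain
#' decimal points regardless of locale.
#'
#' @param features Feature data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  cols <- c("participant_id", "segment_id", "label", "severity",
            feature_columns(), intersect("provenance", names(features)))
  cols <- intersect(cols, names(features))
  utils::write.csv(features[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table CSV
#'
#' @param path Path written by [write_features()].
#' @return Feature data frame.
#' @export
read_features <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
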