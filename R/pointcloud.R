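# Containers for labeled cardiac point clouds and cohort samples, plus the
# plain-text interchange formats (labeled PLY and XYZL).

CLASS_LABELS <- c("LV endocardium" = 1L, "LV epicardium" = 2L,
                  "RV endocardium" = 3L)

#' Construct a multi-class point cloud
#'
#' A multi-class point cloud is the native currency of the shape model: an
#' `n x 3` matrix of coordinates in millimetres together with an integer
#' substructure label per point (1 = LV endocardium, 2 = LV epicardium,
#' 3 = RV endocardium) and the cardiac phase it was observed at.
#'
#' @param points numeric `n x 3` matrix of xyz coordinates (mm).
#' @param labels integer vector of length `n` with values in `{1, 2, 3}`.
#' @param phase `"ED"` (end-diastole) or `"ES"` (end-systole).
#' @return An object of class `mc_point_cloud`.
#' @export
mc_point_cloud <- function(points, labels, phase = c("ED", "ES")) {
  phase <- match.arg(phase)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("`points` must have 3 columns", call. = FALSE)
  if (nrow(points) < 1L) stop("`points` must contain at least one point", call. = FALSE)
  if (!all(is.finite(points))) stop("`points` contains non-finite coordinates", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != nrow(points)) {
    stop("`labels` must have one entry per point", call. = FALSE)
  }
  if (!all(labels %in% 1:3)) stop("`labels` must be in {1, 2, 3}", call. = FALSE)
  if (!all(1:3 %in% labels)) {
    stop("all three substructure labels must be present", call. = FALSE)
  }
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, labels = labels, phase = phase),
            class = "mc_point_cloud")
}

#' @export
print.mc_point_cloud <- function(x, ...) {
  cat(sprintf("<mc_point_cloud> %s phase, %d points (%s)\n", x$phase,
              nrow(x$points),
              paste(sprintf("%s: %d", names(CLASS_LABELS),
                            tabulate(x$labels, 3L)), collapse = ", ")))
  invisible(x)
}

#' Extract the points of one substructure
#'
#' @param cloud an [mc_point_cloud()].
#' @param class_id substructure label (1, 2 or 3).
#' @return numeric matrix of coordinates.
#' @export
cloud_class_points <- function(cloud, class_id) {
  stopifnot(inherits(cloud, "mc_point_cloud"))
  class_id <- assert_count(class_id, "class_id")
  if (!class_id %in% 1:3) stop("`class_id` must be 1, 2 or 3", call. = FALSE)
  cloud$points[cloud$labels == class_id, , drop = FALSE]
}

#' Construct an anatomy sample
#'
#' Pairs the ED and ES clouds of one subject with its cohort metadata: the
#' group label (control, prevalent MI, incident MI), the survival time and
#' censoring flag, and -- for synthetic subjects -- the generative shape
#' factors the anatomy was built from.
#'
#' @param subject_id character scalar.
#' @param ed,es [mc_point_cloud()] objects with matching phases.
#' @param group one of `"control"`, `"prevalent_mi"`, `"incident_mi"`.
#' @param event_time_days nonnegative number, or `NA` when unknown.
#' @param event_observed logical; `TRUE` when the MI event was observed.
#' @param truth optional list of generative shape factors (synthetic only).
#' @return An object of class `anatomy_sample`.
#' @export
anatomy_sample <- function(subject_id, ed, es,
                           group = c("control", "prevalent_mi", "incident_mi"),
                           event_time_days = NA_real_, event_observed = FALSE,
                           truth = NULL) {
  group <- match.arg(group)
  stopifnot(inherits(ed, "mc_point_cloud"), inherits(es, "mc_point_cloud"))
  if (ed$phase != "ED") stop("`ed` must carry phase ED", call. = FALSE)
  if (es$phase != "ES") stop("`es` must carry phase ES", call. = FALSE)
  if (!is.na(event_time_days) && event_time_days < 0) {
    stop("`event_time_days` must be nonnegative", call. = FALSE)
  }
  if (group == "incident_mi" && (!isTRUE(event_observed) || is.na(event_time_days))) {
    stop("incident MI subjects need an observed event time", call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id), ed = ed, es = es,
                 group = group, event_time_days = event_time_days,
                 event_observed = isTRUE(event_observed), truth = truth),
            class = "anatomy_sample")
}

#' @export
print.anatomy_sample <- function(x, ...) {
  cat(sprintf("<anatomy_sample> %s [%s] ED: %d pts, ES: %d pts\n",
              x$subject_id, x$group, nrow(x$ed$points), nrow(x$es$points)))
  invisible(x)
}

# Stack a sample (or single cloud) into the (x, y, z, class, phase) matrix
# consumed by the network kernels.
as_vae_input <- function(x) {
  if (inherits(x, "mc_point_cloud")) {
    return(cbind(x$points, x$labels, if (x$phase == "ES") 1 else 0))
  }
  stopifnot(inherits(x, "anatomy_sample"))
  rbind(cbind(x$ed$points, x$ed$labels, 0),
        cbind(x$es$points, x$es$labels, 1))
}

# ---------------------------------------------------------------------------
# Plain-text interchange formats

#' Write / read a labeled point cloud as XYZL text
#'
#' Four whitespace-separated columns: x, y, z (mm) and the integer class
#' label. Round-trips losslessly to 1e-6 mm.
#'
#' @param cloud an [mc_point_cloud()].
#' @param path file path.
#' @param phase phase tag to attach on reading.
#' @return `write_xyzl` returns `path` invisibly; `read_xyzl` the cloud.
#' @export
write_xyzl <- function(cloud, path) {
  stopifnot(inherits(cloud, "mc_point_cloud"))
  lines <- sprintf("%.6f %.6f %.6f %d", cloud$points[, 1], cloud$points[, 2],
                   cloud$points[, 3], cloud$labels)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_xyzl
#' @export
read_xyzl <- function(path, phase = "ED") {
  m <- as.matrix(read.table(path, col.names = c("x", "y", "z", "label")))
  mc_point_cloud(m[, 1:3, drop = FALSE], as.integer(m[, 4]), phase = phase)
}

#' Write / read a labeled point cloud as ASCII PLY
#'
#' Standard PLY with an extra integer `label` vertex property. Coordinates
#' are written with enough digits to round-trip to 1e-6 mm.
#'
#' @inheritParams write_xyzl
#' @export
write_ply <- function(cloud, path) {
  stopifnot(inherits(cloud, "mc_point_cloud"))
  n <- nrow(cloud$points)
  header <- c("ply", "format ascii 1.0",
              sprintf("comment cardiopoint labeled point cloud (%s)", cloud$phase),
              sprintf("element vertex %d", n),
              "property double x", "property double y", "property double z",
              "property int label", "end_header")
  body <- sprintf("%.8f %.8f %.8f %d", cloud$points[, 1], cloud$points[, 2],
                  cloud$points[, 3], cloud$labels)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path, phase = "ED") {
  lines <- readLines(path)
  if (length(lines) < 3L || lines[1] != "ply") stop("not a PLY file", call. = FALSE)
  hdr_end <- match("end_header", lines)
  if (is.na(hdr_end)) stop("PLY header not terminated", call. = FALSE)
  vline <- grep("^element vertex ", lines[seq_len(hdr_end)], value = TRUE)
  n <- as.integer(sub("^element vertex ", "", vline[1]))
  props <- sub("^property \\S+ ", "",
               grep("^property ", lines[seq_len(hdr_end)], value = TRUE))
  need <- c("x", "y", "z", "label")
  idx <- match(need, props)
  if (anyNA(idx)) stop("PLY file lacks x/y/z/label vertex properties", call. = FALSE)
  body <- lines[(hdr_end + 1L):(hdr_end + n)]
  m <- matrix(scan(text = body, quiet = TRUE), nrow = n, byrow = TRUE)
  mc_point_cloud(m[, idx[1:3], drop = FALSE], as.integer(m[, idx[4]]),
                 phase = phase)
}

#' Write / read cohort metadata as CSV
#'
#' One row per subject: id, group, survival time, censoring flag, and the
#' generative truth factors when present.
#'
#' @param samples list of [anatomy_sample()] objects.
#' @param path CSV file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   a tibble.
#' @export
write_cohort_csv <- function(samples, path) {
  tb <- cohort_table(samples)
  write.csv(as.data.frame(tb), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Tabulate cohort metadata
#'
#' @param samples list of [anatomy_sample()] objects.
#' @return A tibble with one row per subject.
#' @export
cohort_table <- function(samples) {
  stopifnot(length(samples) >= 1L)
  rows <- lapply(samples, function(s) {
    base <- tibble::tibble(subject_id = s$subject_id, group = s$group,
                           event_time_days = s$event_time_days,
                           event_observed = s$event_observed)
    if (!is.null(s$truth)) {
      tr <- tibble::as_tibble(s$truth[c("scale", "elongation", "basal_tilt",
                                        "wall_thickness", "rv_size",
                                        "ef_target", "mi_flag", "risk_score")])
      names(tr) <- paste0("truth_", names(tr))
      base <- cbind(base, tr)
    }
    base
  })
  tibble::as_tibble(do.call(rbind, rows))
}
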