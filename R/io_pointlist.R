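#' Landmark point lists
#'
#' Landmarks are role-tagged 2D physical points (mm). A point list for one
#' modality holds the circumferential landmarks placed around the specimen
#' boundary and up to three fiducial markers (cannula tracks along the
#' specimen's long axis), each fiducial role occurring at most once.
#'
#' @param label character labels.
#' @param role one of `"circumferential"`, `"fiducial_left"`,
#'   `"fiducial_middle"`, `"fiducial_right"` per point.
#' @param x,y physical coordinates in mm (internal frame: x rightward,
#'   y downward, origin at the image corner).
#' @param modality `"US"` or `"WSI"`.
#' @return A `data.frame` with columns `label`, `role`, `x`, `y`, `modality`.
#' @export
landmark_list <- function(label, role, x, y, modality = "US") {
  roles_ok <- c("circumferential", "fiducial_left", "fiducial_middle", "fiducial_right")
  bad <- setdiff(unique(role), roles_ok)
  if (length(bad))
    stop_sp("unknown landmark role(s) %s; allowed roles: %s",
            paste(sQuote(bad), collapse = ", "), paste(roles_ok, collapse = ", "))
  if (!all(modality %in% c("US", "WSI")))
    stop_sp("modality must be 'US' or 'WSI'")
  fid <- role[role != "circumferential"]
  if (anyDuplicated(fid))
    stop_sp("duplicate fiducial role(s): %s", paste(unique(fid[duplicated(fid)]), collapse = ", "))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_sp("landmark positions must be finite")
  data.frame(label = as.character(label), role = as.character(role),
             x = as.numeric(x), y = as.numeric(y),
             modality = rep_len(as.character(modality), length(x)),
             stringsAsFactors = FALSE)
}

parse_role <- function(label, desc = "") {
  roles_ok <- c("circumferential", "fiducial_left", "fiducial_middle", "fiducial_right")
  cand <- ifelse(nzchar(desc), desc, label)
  role <- rep(NA_character_, length(cand))
  for (r in roles_ok) role[startsWith(cand, r)] <- r
  role[is.na(role) & grepl("^circ", cand)] <- "circumferential"
  if (anyNA(role))
    stop_sp("unknown landmark role label(s) %s; allowed roles: %s",
            paste(sQuote(unique(cand[is.na(role)])), collapse = ", "),
            paste(roles_ok, collapse = ", "))
  role
}

# Internal frame <-> Slicer RAS: (x, y) maps to (R, A) = (x, -y), S = 0.
# The internal y axis points downward (image rows); RAS A points anteriorly.
to_ras <- function(x, y) cbind(R = x, A = -y, S = 0)
from_ras <- function(r, a) cbind(x = r, y = -a)

#' Read / write 3D Slicer markups point lists
#'
#' Supports the two Slicer markups dialects: FCSV (comma-separated with `#`
#' header lines) and markups JSON. Both store RAS coordinates; the (R, A)
#' plane is mapped to the internal frame as `(x, -y)`. Roles are carried in
#' the description column (FCSV) / `description` field (JSON) and fall back
#' to the label prefix.
#'
#' @param path file ending in `.fcsv`, `.json` or `.mrk.json`.
#' @param landmarks a landmark `data.frame` as from [landmark_list()].
#' @param modality modality tag to assign on read.
#' @param format `"auto"` (by extension), `"fcsv"` or `"json"` to force a
#'   dialect.
#' @export
read_pointlist <- function(path, modality = "US", format = c("auto", "fcsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_sp("read_pointlist: file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.fcsv$", path, ignore.case = TRUE)) "fcsv" else "json"
  if (format == "fcsv") {
    lines <- readLines(path)
    body <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (!length(body)) stop_sp("read_pointlist: no data rows in %s", path)
    df <- utils::read.csv(text = body, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 12L) stop_sp("read_pointlist: FCSV row has %d columns, expected >= 12", ncol(df))
    xy <- from_ras(as.numeric(df[[2]]), as.numeric(df[[3]]))
    label <- as.character(df[[12]])
    desc <- if (ncol(df) >= 13L) as.character(df[[13]]) else rep("", nrow(df))
    desc[is.na(desc)] <- ""
  } else {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    cps <- doc$markups[[1]]$controlPoints
    if (is.null(cps)) stop_sp("read_pointlist: no controlPoints in markups JSON %s", path)
    pos <- t(vapply(cps, function(p) as.numeric(unlist(p$position)), numeric(3)))
    xy <- from_ras(pos[, 1], pos[, 2])
    label <- vapply(cps, function(p) p$label %||% "", "")
    desc <- vapply(cps, function(p) p$description %||% "", "")
  }
  landmark_list(label, parse_role(label, desc), xy[, 1], xy[, 2], modality)
}

#' @rdname read_pointlist
#' @export
write_pointlist <- function(landmarks, path, format = c("auto", "fcsv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.fcsv$", path, ignore.case = TRUE)) "fcsv" else "json"
  ras <- to_ras(landmarks$x, landmarks$y)
  if (format == "fcsv") {
    hdr <- c("# Markups fiducial file version = 4.11",
             "# CoordinateSystem = RAS",
             "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID")
    rows <- sprintf("vtkMRMLMarkupsFiducialNode_%d,%.17g,%.17g,%.17g,0,0,0,1,1,1,0,%s,%s,",
                    seq_len(nrow(landmarks)) - 1L, ras[, 1], ras[, 2], ras[, 3],
                    landmarks$label, landmarks$role)
    writeLines(c(hdr, rows), path)
  } else {
    cps <- lapply(seq_len(nrow(landmarks)), function(i) {
      list(id = as.character(i), label = landmarks$label[i],
           description = landmarks$role[i],
           position = as.numeric(ras[i, ]),
           orientation = c(-1, 0, 0, 0, -1, 0, 0, 0, 1),
           selected = TRUE, locked = FALSE, visibility = TRUE,
           positionStatus = "defined")
    })
    doc <- list(
      `@schema` = "https://raw.githubusercontent.com/slicer/slicer/master/Modules/Loadable/Markups/Resources/Schema/markups-schema-v1.0.3.json#",
      markups = list(list(type = "Fiducial", coordinateSystem = "RAS",
                          coordinateUnits = "mm", controlPoints = cps)))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
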