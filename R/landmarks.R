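#' Canonical nasolabial landmark identifiers
#'
#' The 33 anatomical landmarks of the nasolabial region used throughout the
#' package: nasion (n), subnasale (sn), pronasale (prn), alar curvature base
#' (acbR/acbL), alare (alR/alL), columella high points (cR/cL), columellar
#' median high point (cM), inner/outer alare (aliR/aliL, aloR/aloL), subalare
#' (sbalR/sbalL), medial alar base (mabR/mabL), columella base (cbR/cbL),
#' cheilion (chR/chL), crista philtri (cphR/cphL), labrale superius (ls),
#' stomion (sto), vermillion-mucosal junctions (vmjR/vmjL/vmjM), prolabiale
#' (prl), superior labial sulcus (sls) and lateral vermillion (lvR/lvL).
#'
#' @return Character vector of the 33 canonical landmark ids.
#' @export
#' @examples
#' length(landmark_ids())  # 33
landmark_ids <- function() {
  c("n", "sn", "prn", "acbR", "acbL", "alR", "alL", "cR", "cL", "cM",
    "aliR", "aliL", "aloR", "aloL", "sbalR", "sbalL", "mabR", "mabL",
    "cbR", "cbL", "chR", "chL", "cphR", "cphL", "ls", "sto",
    "vmjR", "vmjL", "vmjM", "prl", "sls", "lvR", "lvL")
}

#' Construct a landmark set
#'
#' @param coords Numeric matrix with 3 columns (x, y, z in mm) and rownames
#'   drawn from [landmark_ids()], or a named list of length-3 numeric vectors.
#' @param virtual Character vector of ids whose placement is virtual (e.g.
#'   `sto` estimated on an open-mouth scan).
#' @return An object of class `naso_landmarks`: a numeric matrix (n x 3,
#'   rownames = ids, columns x/y/z) with attribute `virtual`.
#' @export
landmark_set <- function(coords, virtual = character()) {
  if (is.list(coords)) {
    ids <- names(coords)
    coords <- do.call(rbind, lapply(coords, as.numeric))
    rownames(coords) <- ids
  }
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("landmark coordinates must have 3 columns (x, y, z)")
  storage.mode(coords) <- "double"
  ids <- rownames(coords)
  if (is.null(ids)) stop("landmark coordinates must be named by id")
  unknown <- setdiff(ids, landmark_ids())
  if (length(unknown))
    stop("unknown landmark id(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(ids))
    stop("duplicated landmark id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!all(is.finite(coords)))
    stop("landmark coordinates must be finite")
  bad <- setdiff(virtual, ids)
  if (length(bad))
    stop("virtual flag for absent landmark(s): ", paste(bad, collapse = ", "))
  colnames(coords) <- c("x", "y", "z")
  structure(coords, virtual = as.character(virtual),
            class = c("naso_landmarks", "matrix", "array"))
}

#' @export
print.naso_landmarks <- function(x, ...) {
  miss <- missing_landmarks(x)
  cat(sprintf("<naso_landmarks> %d of 33 landmarks%s\n", nrow(x),
              if (length(miss) == 0L) " (complete)" else ""))
  if (length(miss))
    cat("  missing:", paste(miss, collapse = ", "), "\n")
  v <- attr(x, "virtual")
  if (length(v)) cat("  virtual:", paste(v, collapse = ", "), "\n")
  print(unclass(structure(x, virtual = NULL)), ...)
  invisible(x)
}

#' Ids absent from a landmark set
#' @param lm A `naso_landmarks` object.
#' @return Character vector of canonical ids not present.
#' @export
missing_landmarks <- function(lm) setdiff(landmark_ids(), rownames(lm))

#' Is a landmark set complete?
#' @param lm A `naso_landmarks` object.
#' @return TRUE when all 33 canonical landmarks are present.
#' @export
is_complete <- function(lm) length(missing_landmarks(lm)) == 0L

lm_has <- function(lm, ids) all(ids %in% rownames(lm))
lm_pt <- function(lm, id) as.numeric(lm[id, ])

#' Read a landmark file
#'
#' Two dialects are supported. JSON:
#' `{"landmarks": {"<id>": [x, y, z], ...}, "virtual": ["sto", ...]}`.
#' CSV: header `id,x,y,z,virtual` with one row per landmark, coordinates in
#' mm, and `virtual` a logical (optional column). Unknown ids are rejected
#' with the offending id named; partial sets load with the missing ids
#' reported via [missing_landmarks()].
#'
#' @param path Path to a `.json` or `.csv` landmark file.
#' @return A `naso_landmarks` object.
#' @export
load_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (is.null(doc$landmarks)) stop("landmark JSON lacks a 'landmarks' field")
    lms <- doc$landmarks
    coords <- do.call(rbind, lapply(lms, function(p) {
      p <- suppressWarnings(as.numeric(p))
      if (length(p) != 3L || anyNA(p)) stop("malformed coordinates in ", path)
      p
    }))
    rownames(coords) <- names(lms)
    virtual <- as.character(if (is.null(doc$virtual)) character() else doc$virtual)
  } else if (ext == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "x", "y", "z")
    if (!all(need %in% names(tab)))
      stop("landmark CSV must have columns id,x,y,z")
    coords <- as.matrix(tab[, c("x", "y", "z")])
    if (!is.numeric(coords) || anyNA(coords))
      stop("malformed coordinates in ", path)
    rownames(coords) <- tab$id
    virtual <- if ("virtual" %in% names(tab))
      tab$id[as.logical(tab$virtual) %in% TRUE] else character()
  } else stop("unsupported landmark format: .", ext, " (expected JSON or CSV)")
  landmark_set(coords, virtual = virtual)
}

#' Write a landmark file
#'
#' Inverse of [load_landmarks()]; the JSON/CSV dialects round-trip ids,
#' coordinates and virtual flags losslessly.
#'
#' @param lm A `naso_landmarks` object.
#' @param path Output path; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    lms <- lapply(seq_len(nrow(lm)), function(i) as.numeric(lm[i, ]))
    names(lms) <- rownames(lm)
    jsonlite::write_json(list(landmarks = lms,
                              virtual = as.character(attr(lm, "virtual"))),
                         path, digits = I(17), auto_unbox = FALSE)
  } else if (ext == "csv") {
    fmt <- function(v) sprintf("%.17g", v)  # exact double round-trip
    tab <- data.frame(id = rownames(lm), x = fmt(lm[, 1]), y = fmt(lm[, 2]),
                      z = fmt(lm[, 3]),
                      virtual = rownames(lm) %in% attr(lm, "virtual"))
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  } else stop("unsupported landmark format: .", ext)
  invisible(path)
}

#' Mirror a landmark set across a plane
#'
#' Reflects every coordinate across the given plane (default the plane x = 0)
#' and swaps every R-suffixed id with its L counterpart, so that a mirrored
#' set remains anatomically labelled.
#'
#' @param lm A `naso_landmarks` object.
#' @param plane A `naso_plane` (see [plane3()]); default the plane x = 0.
#' @return The mirrored `naso_landmarks`.
#' @export
mirror_landmarks <- function(lm, plane = plane3(c(0, 0, 0), c(1, 0, 0))) {
  pts <- reflect_points(unclass(lm)[, , drop = FALSE], plane)
  ids <- rownames(lm)
  swapped <- swap_side_ids(ids)
  rownames(pts) <- swapped
  virt <- swap_side_ids(attr(lm, "virtual"))
  landmark_set(pts[order(match(swapped, landmark_ids())), , drop = FALSE],
               virtual = virt)
}

swap_side_ids <- function(ids) {
  out <- ids
  r <- grepl("R$", ids)
  l <- grepl("L$", ids)
  out[r] <- sub("R$", "L", ids[r])
  out[l] <- sub("L$", "R", ids[l])
  out
}
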