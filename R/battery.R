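battery_skeleton <- function(ids) {
  reg <- registry()
  data.frame(id = ids,
             name = vapply(reg[ids], `[[`, "", "name"),
             kind = vapply(reg[ids], `[[`, "", "kind"),
             value = NA_real_,
             units = vapply(reg[ids], function(e)
               switch(e$kind, index = "", angle3 = "deg", angle2dir = "deg", "mm"), ""),
             status = "skipped-missing-input",
             reason = NA_character_,
             row.names = NULL, stringsAsFactors = FALSE)
}

as_battery <- function(tab, curves = list()) {
  structure(tab, curves = curves, class = c("naso_battery", "data.frame"))
}

#' @export
print.naso_battery <- function(x, ...) {
  ok <- sum(x$status == "computed")
  cat(sprintf("<naso_battery> %d/%d parameters computed\n", ok, nrow(x)))
  show <- x[, c("id", "name", "value", "units", "status")]
  show$value <- ifelse(show$units == "" & !is.na(show$value),
                       sprintf("%.4f", show$value),
                       ifelse(is.na(show$value), NA, sprintf("%.2f", show$value)))
  print.data.frame(show, row.names = FALSE, ...)
  invisible(x)
}

merge_batteries <- function(...) {
  parts <- list(...)
  tab <- do.call(rbind, lapply(parts, function(p) as.data.frame(p)))
  curves <- do.call(c, lapply(parts, function(p) attr(p, "curves")))
  ord <- order(match(substr(tab$id, 1, 1), c("D", "S", "A", "I")),
               as.integer(sub("^[DSAI]", "", tab$id)))
  as_battery(tab[ord, , drop = FALSE], curves)
}

#' Compute the distance parameters (D1-D32)
#'
#' Direct lengths between landmark pairs plus the four perpendicular
#' constructions: effective nasal length D4 (prn to the n-sn line), dimple
#' depth D16 (sls to the prl-sn line) and vermillion convexities D27/D28
#' (lvR/lvL to the ch-cph line of their side). Parameters with absent
#' landmarks are skipped with a reason, never silently dropped.
#'
#' @param lm A `naso_landmarks` (any subset).
#' @return A partial `naso_battery` with the 32 D rows.
#' @export
compute_distances <- function(lm) {
  reg <- registry()
  ids <- names(reg)[vapply(reg, function(e)
    e$kind %in% c("distance", "perpendicular"), TRUE)]
  tab <- battery_skeleton(ids)
  for (r in seq_len(nrow(tab))) {
    e <- reg[[tab$id[r]]]
    if (!lm_has(lm, e$inputs)) {
      tab$reason[r] <- paste("missing", paste(setdiff(e$inputs, rownames(lm)),
                                              collapse = ","))
      next
    }
    val <- tryCatch({
      if (e$kind == "distance")
        euclidean_distance(lm_pt(lm, e$inputs[1]), lm_pt(lm, e$inputs[2]))
      else
        perpendicular_length(lm_pt(lm, e$point), lm_pt(lm, e$line[1]),
                             lm_pt(lm, e$line[2]))
    }, error = function(err) err)
    if (inherits(val, "error")) {
      tab$status[r] <- "skipped-missing-input"
      tab$reason[r] <- conditionMessage(val)
    } else {
      tab$value[r] <- val
      tab$status[r] <- "computed"
      tab$reason[r] <- NA
    }
  }
  as_battery(tab)
}

#' Compute the surface-curve parameters (S1-S32)
#'
#' Every S-parameter is a geodesic surface curve through its registry
#' waypoints; S6/S7 are closed loops through columella base, medial alar
#' base and inner alare. Composite curves (S3, S12, S14, S18, ...) are
#' concatenations of the same per-segment geodesics, so their lengths are
#' exactly additive (S3 = S1 + S2, S12 = S10 + S11).
#'
#' @param mesh A `naso_mesh`.
#' @param lm A `naso_landmarks`.
#' @param graph Optional precomputed [geodesic_graph()] (built once here
#'   otherwise and reused across all 32 curves).
#' @param tol_project Waypoint on-surface tolerance in mm (default 0.5).
#' @param probe_saddles Saddle probing for every curve (see
#'   [geodesic_curve()]; default TRUE).
#' @return A partial `naso_battery` with the 32 S rows; curve polylines in
#'   `attr(, "curves")`.
#' @export
compute_surface_curves <- function(mesh, lm, graph = NULL, tol_project = 0.5,
                                   probe_saddles = TRUE) {
  reg <- registry()
  ids <- names(reg)[vapply(reg, function(e) e$kind == "surface_curve", TRUE)]
  tab <- battery_skeleton(ids)
  curves <- list()
  if (is.null(graph)) graph <- geodesic_graph(mesh)
  for (r in seq_len(nrow(tab))) {
    e <- reg[[tab$id[r]]]
    if (!lm_has(lm, e$inputs)) {
      tab$reason[r] <- paste("missing", paste(setdiff(e$inputs, rownames(lm)),
                                              collapse = ","))
      next
    }
    cv <- tryCatch(
      geodesic_curve(mesh, lm[e$waypoints, , drop = FALSE], closed = e$closed,
                     graph = graph, tol_project = tol_project,
                     probe_saddles = probe_saddles),
      error = function(err) err)
    if (inherits(cv, "error")) {
      tab$reason[r] <- conditionMessage(cv)
    } else {
      tab$value[r] <- cv$length
      tab$status[r] <- "computed"
      tab$reason[r] <- NA
      curves[[tab$id[r]]] <- cv
    }
  }
  as_battery(tab, curves)
}

#' Compute the angle parameters (A1, A2)
#'
#' A1, the columellar angle, is the two-directional angle between the
#' cM-to-sn direction and the commissure line chR-chL; A2, the vermillion
#' angle, is the three-point angle chR-ls-chL with ls as the angle point.
#'
#' @param lm A `naso_landmarks`.
#' @return A partial `naso_battery` with the 2 A rows.
#' @export
compute_angles <- function(lm) {
  reg <- registry()
  tab <- battery_skeleton(c("A1", "A2"))
  for (r in seq_len(nrow(tab))) {
    e <- reg[[tab$id[r]]]
    if (!lm_has(lm, e$inputs)) {
      tab$reason[r] <- paste("missing", paste(setdiff(e$inputs, rownames(lm)),
                                              collapse = ","))
      next
    }
    val <- tryCatch({
      if (e$kind == "angle2dir")
        two_direction_angle(lm_pt(lm, e$dir1[2]) - lm_pt(lm, e$dir1[1]),
                            lm_pt(lm, e$dir2[2]) - lm_pt(lm, e$dir2[1]))
      else
        three_point_angle(lm_pt(lm, e$rays[1]), lm_pt(lm, e$vertex),
                          lm_pt(lm, e$rays[2]))
    }, error = function(err) err)
    if (inherits(val, "error")) {
      tab$reason[r] <- conditionMessage(val)
    } else {
      tab$value[r] <- val; tab$status[r] <- "computed"; tab$reason[r] <- NA
    }
  }
  as_battery(tab)
}

#' Compute the 18 indices from measured parameters
#'
#' Ratio and average formulas over D/S values (e.g. vertical nasal
#' convexity = S3/D1, mouth-to-nose symmetry = mean of the lateral and
#' central symmetry ratios, soft-tissue mouth-to-nose = D15 over the wider
#' of nasal base and alar width). An index is present only when all its
#' inputs were computed; a zero denominator yields an explicit
#' "undefined-index" status, never a silent NaN.
#'
#' @param partial A `naso_battery` holding the computed D/S (and index)
#'   inputs, e.g. the merge of [compute_distances()] and
#'   [compute_surface_curves()].
#' @return A partial `naso_battery` with the 18 I rows.
#' @export
compute_indices <- function(partial) {
  reg <- registry()
  ids <- names(reg)[vapply(reg, function(e) e$kind == "index", TRUE)]
  tab <- battery_skeleton(ids)
  vals <- stats::setNames(partial$value, partial$id)
  ok <- stats::setNames(partial$status == "computed", partial$id)
  ival <- c()
  for (r in seq_len(nrow(tab))) {
    e <- reg[[tab$id[r]]]
    if (!is.null(e$of)) {
      if (all(e$of %in% names(ival))) {
        tab$value[r] <- mean(ival[e$of]); tab$status[r] <- "computed"
        tab$reason[r] <- NA
        ival[e$id] <- tab$value[r]
      } else tab$reason[r] <- paste("missing", paste(setdiff(e$of, names(ival)),
                                                     collapse = ","))
      next
    }
    need <- c(e$num, e$den)
    have <- need %in% names(vals) & !is.na(ok[need]) & ok[need]
    if (!all(have)) {
      tab$reason[r] <- paste("missing", paste(need[!have], collapse = ","))
      next
    }
    den <- if (e$den_rule == "max") max(vals[e$den]) else sum(vals[e$den])
    if (den == 0) {
      tab$status[r] <- "undefined-index"
      tab$reason[r] <- "zero denominator"
      next
    }
    tab$value[r] <- sum(vals[e$num]) / den
    tab$status[r] <- "computed"
    tab$reason[r] <- NA
    ival[e$id] <- tab$value[r]
  }
  as_battery(tab)
}

#' Compute the full 84-parameter battery
#'
#' Union of [compute_distances()], [compute_surface_curves()],
#' [compute_angles()] and [compute_indices()]; a complete landmark set on a
#' connected mesh yields 84 computed parameters, partial input yields the
#' computable subset with per-parameter skip reasons.
#'
#' @inheritParams compute_surface_curves
#' @return A `naso_battery` with 84 rows.
#' @export
compute_battery <- function(mesh, lm, graph = NULL, tol_project = 0.5,
                            probe_saddles = TRUE) {
  if (is.null(graph)) graph <- geodesic_graph(mesh)
  d <- compute_distances(lm)
  s <- compute_surface_curves(mesh, lm, graph = graph,
                              tol_project = tol_project,
                              probe_saddles = probe_saddles)
  a <- compute_angles(lm)
  i <- compute_indices(merge_batteries(d, s))
  merge_batteries(d, s, a, i)
}

#' Derive constructively defined landmarks
#'
#' Computes the landmarks the measurement scheme defines geometrically
#' rather than visually: pronasale prn (point of the n-sn surface curve
#' furthest from the n-sn line), superior labial sulcus sls (point of the
#' sn-prl curve furthest from the sn-prl line), lateral vermillion lvR/lvL
#' (point of the ch-cph-ls vermillion border curve furthest from the ch-ls
#' line) and the columellar median high point cM (intersection of the
#' cR-cL and prn-sn surface curves). User-supplied values are kept; the
#' derived positions are reported alongside for quality control.
#'
#' @param mesh A `naso_mesh`.
#' @param lm A `naso_landmarks` containing the anchors of each rule.
#' @param graph Optional precomputed [geodesic_graph()].
#' @param flat_tol Max perpendicular distance in mm under which a derived
#'   extremum is flagged degenerate (e.g. "no dimple"; default 0.05).
#' @return List: `landmarks` (`naso_landmarks` of the derivable points),
#'   `qc` (data.frame: id, derived coordinates, distance to the
#'   user-supplied position in mm when present, note).
#' @export
derive_constructive_landmarks <- function(mesh, lm, graph = NULL,
                                          flat_tol = 0.05) {
  if (is.null(graph)) graph <- geodesic_graph(mesh)
  out <- list(); notes <- list()
  farthest_on_curve <- function(waypoints, a, b) {
    cv <- geodesic_curve(mesh, lm[waypoints, , drop = FALSE], graph = graph)
    d <- apply(cv$points, 1, perpendicular_length,
               a = lm_pt(lm, a), b = lm_pt(lm, b))
    list(point = cv$points[which.max(d), ], dist = max(d))
  }
  if (lm_has(lm, c("n", "sn"))) {
    r <- farthest_on_curve(c("n", "sn"), "n", "sn")
    out$prn <- r$point
    notes$prn <- if (r$dist < flat_tol) "degenerate: flat nasal profile" else ""
  }
  if (lm_has(lm, c("sn", "prl"))) {
    r <- farthest_on_curve(c("sn", "prl"), "sn", "prl")
    out$sls <- r$point
    notes$sls <- if (r$dist < flat_tol) "degenerate: no dimple" else ""
  }
  if (lm_has(lm, c("chR", "cphR", "ls"))) {
    r <- farthest_on_curve(c("chR", "cphR", "ls"), "chR", "ls")
    out$lvR <- r$point
    notes$lvR <- if (r$dist < flat_tol) "degenerate: flat vermillion" else ""
  }
  if (lm_has(lm, c("chL", "cphL", "ls"))) {
    r <- farthest_on_curve(c("chL", "cphL", "ls"), "chL", "ls")
    out$lvL <- r$point
    notes$lvL <- if (r$dist < flat_tol) "degenerate: flat vermillion" else ""
  }
  if (lm_has(lm, c("cR", "cL", "prn", "sn"))) {
    c1 <- geodesic_curve(mesh, lm[c("cR", "cL"), , drop = FALSE], graph = graph)
    c2 <- geodesic_curve(mesh, lm[c("prn", "sn"), , drop = FALSE], graph = graph)
    pr <- polyline_closest_pair(c1$points, c2$points)
    out$cM <- (pr$p1 + pr$p2) / 2
    notes$cM <- if (pr$dist > 1.0)
      sprintf("curves do not intersect (gap %.2f mm)", pr$dist) else ""
  }
  if (!length(out))
    return(list(landmarks = NULL,
                qc = data.frame(id = character(), note = character())))
  pts <- do.call(rbind, out)
  rownames(pts) <- names(out)
  qc <- data.frame(id = names(out), x = pts[, 1], y = pts[, 2], z = pts[, 3],
                   user_discrepancy_mm = vapply(names(out), function(id)
                     if (lm_has(lm, id))
                       euclidean_distance(lm_pt(lm, id), out[[id]])
                     else NA_real_, 0),
                   note = unlist(notes), row.names = NULL,
                   stringsAsFactors = FALSE)
  list(landmarks = landmark_set(pts), qc = qc)
}

# Closest pair of points between two polylines (segment-to-segment scan).
polyline_closest_pair <- function(p1, p2) {
  best <- list(dist = Inf)
  for (i in seq_len(nrow(p1) - 1L)) {
    a0 <- p1[i, ]; a1 <- p1[i + 1L, ]
    for (j in seq_len(nrow(p2) - 1L)) {
      r <- segment_segment_closest(a0, a1, p2[j, ], p2[j + 1L, ])
      if (r$dist < best$dist) best <- r
    }
  }
  best
}

segment_segment_closest <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a == 0 && e == 0) return(list(p1 = p1, p2 = p2,
                                    dist = sqrt(sum(r * r))))
  if (a == 0) { s <- 0; t_ <- min(max(f / e, 0), 1) }
  else {
    c_ <- sum(d1 * r)
    if (e == 0) { t_ <- 0; s <- min(max(-c_ / a, 0), 1) }
    else {
      b <- sum(d1 * d2); den <- a * e - b * b
      s <- if (den != 0) min(max((b * f - c_ * e) / den, 0), 1) else 0
      t_ <- (b * s + f) / e
      if (t_ < 0) { t_ <- 0; s <- min(max(-c_ / a, 0), 1) }
      else if (t_ > 1) { t_ <- 1; s <- min(max((b - c_) / a, 0), 1) }
    }
  }
  cp1 <- p1 + s * d1; cp2 <- p2 + t_ * d2
  list(p1 = cp1, p2 = cp2, dist = sqrt(sum((cp1 - cp2)^2)))
}

#' Write a battery report
#'
#' One record per parameter (id, name, kind, value, units, status); CSV or
#' JSON. Values round-trip bit-exactly through [read_report()].
#'
#' @param result A `naso_battery`.
#' @param path Output path.
#' @param format "csv" or "json" (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = tools::file_ext(path)) {
  tab <- as.data.frame(result)[, c("id", "name", "kind", "value", "units",
                                   "status", "reason")]
  format <- tolower(format)
  if (format == "csv") {
    utils::write.csv(format_report_csv(tab), path, row.names = FALSE,
                     na = "")
  } else if (format == "json") {
    jsonlite::write_json(tab, path, digits = I(17), na = "null", auto_unbox = FALSE,
                         dataframe = "rows")
  } else stop("unsupported report format: ", format)
  invisible(path)
}

format_report_csv <- function(tab) {
  tab$value <- vapply(tab$value, function(v)
    if (is.na(v)) NA_character_ else sprintf("%.17g", v), "")
  tab
}

#' Read a battery report back
#' @param path A report written by [write_report()].
#' @return A `naso_battery`.
#' @export
read_report <- function(path) {
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(value = "character"))
  } else if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else stop("unsupported report format: .", ext)
  if (is.character(tab$value)) tab$value <- as.numeric(tab$value)
  if (nrow(tab)) {
    tab$reason <- if (is.null(tab$reason)) NA_character_ else
      ifelse(tab$reason %in% c("", NA), NA_character_, tab$reason)
  }
  as_battery(tab)
}
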