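#' Classify the alar base type
#'
#' Types the alar base of each side from the spatial relationship of the
#' medial alar base (mab), the columella high point (c) and the columella
#' base (cb): Type I when mab is more lateral than c, Type II when mab is
#' more medial than c, Type III when mab transitions directly into cb.
#' "More lateral" is formalized as a larger unsigned offset from the
#' morphological midsagittal plane (through n, sn, prn); the Type III
#' "direct transition" is detected first, as mab-cb coincidence within
#' `tol_coincide`. Offset differences inside the `tol_compare` dead-zone
#' give "indeterminate" rather than a forced I/II call.
#'
#' @param lm A `naso_landmarks` with n, sn, prn and, per side, mab, c, cb.
#' @param tol_coincide mab-cb coincidence tolerance in mm (default 0.5).
#' @param tol_compare Lateral-offset comparison dead-zone in mm (default 0.1).
#' @return A `naso_alar` report: per side the type ("I", "II", "III" or
#'   "indeterminate"), the |lateral offsets| of mab, c, cb, the mab-cb
#'   separation and the margin; `overall` when both sides agree, else
#'   "discordant".
#' @export
classify_alar_base <- function(lm, tol_coincide = 0.5, tol_compare = 0.1) {
  need <- c("n", "sn", "prn", "mabR", "mabL", "cR", "cL", "cbR", "cbL")
  miss <- setdiff(need, rownames(lm))
  if (length(miss))
    stop("missing landmark(s) for alar typing: ", paste(miss, collapse = ", "))
  pl <- midsagittal_plane(lm)
  side <- function(sfx) {
    mab <- lm_pt(lm, paste0("mab", sfx))
    c_ <- lm_pt(lm, paste0("c", sfx))
    cb <- lm_pt(lm, paste0("cb", sfx))
    sep <- euclidean_distance(mab, cb)
    off <- c(mab = abs(lateral_offset(pl, mab)),
             c = abs(lateral_offset(pl, c_)),
             cb = abs(lateral_offset(pl, cb)))
    margin <- off["mab"] - off["c"]
    type <- if (sep < tol_coincide) "III"
            else if (margin > tol_compare) "I"
            else if (margin < -tol_compare) "II"
            else "indeterminate"
    list(type = type, offsets_mm = off, mab_cb_separation_mm = sep,
         margin_mm = unname(margin))
  }
  r <- side("R"); l <- side("L")
  structure(list(R = r, L = l,
                 overall = if (r$type == l$type) r$type else "discordant",
                 tol_coincide = tol_coincide, tol_compare = tol_compare),
            class = "naso_alar")
}

#' @export
print.naso_alar <- function(x, ...) {
  cat("<naso_alar> alar base classification\n")
  for (s in c("R", "L"))
    cat(sprintf("  %s: Type %-13s |lat(mab)| %.2f  |lat(c)| %.2f  mab-cb %.2f mm\n",
                s, x[[s]]$type, x[[s]]$offsets_mm["mab"], x[[s]]$offsets_mm["c"],
                x[[s]]$mab_cb_separation_mm))
  cat("  overall:", x$overall, "\n")
  invisible(x)
}
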