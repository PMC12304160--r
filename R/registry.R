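#' The 84-parameter registry
#'
#' Machine-readable definitions of the full measurement battery: 32
#' distances (D1-D32; direct lengths plus the four perpendicular
#' constructions for effective nasal length, dimple depth and the two
#' vermillion convexities), 32 on-surface curves (S1-S32, including the
#' closed nostril circumferences S6/S7 and the composite curves S3, S12,
#' S14 and S18), 2 angles (A1 two-directional, A2 three-point) and 18
#' dimensionless indices.
#'
#' @return A `naso_registry`: named list of parameter definitions, each a
#'   list with `id`, `name`, `kind` (distance / perpendicular /
#'   surface_curve / angle3 / angle2dir / index), `inputs` (landmark ids
#'   for measured parameters, parameter ids for indices) and a
#'   kind-specific recipe (`waypoints`+`closed` for curves, `point`/`line`
#'   for perpendiculars, `num`/`den` or `of` for indices).
#' @export
#' @examples
#' reg <- registry()
#' table(vapply(reg, `[[`, "", "kind"))
registry <- function() {
  if (!is.null(.registry_cache$reg)) return(.registry_cache$reg)
  def <- list()
  dist2 <- registry_distance_pairs()
  dist_names <- c(
    D1 = "Nasal height", D2 = "Nasal base width", D3 = "Nasal alar width",
    D4 = "Effective nasal length",
    D5 = "Right alar base to pronasale", D6 = "Left alar base to pronasale",
    D7 = "Right alar thickness", D8 = "Left alar thickness",
    D9 = "Caudal nasal base width",
    D10 = "Right nostril floor width", D11 = "Left nostril floor width",
    D12 = "Right lateral columella length", D13 = "Left lateral columella length",
    D14 = "Median sagittal columella length", D15 = "Mouth width",
    D16 = "Dimple depth",
    D17 = "Vertical heights of the right lateral lip",
    D18 = "Vertical heights of the left lateral lip",
    D19 = "Vertical heights of the right medial lip (Philtrum)",
    D20 = "Vertical heights of the left medial lip (Philtrum)",
    D21 = "Upper lip height", D22 = "Philtrum length",
    D23 = "Right vermillion length", D24 = "Left vermillion length",
    D25 = "Transverse lengths of the right lateral lip element",
    D26 = "Transverse lengths of the left lateral lip element",
    D27 = "Right vermillion convexity", D28 = "Left vermillion convexity",
    D29 = "Right lateral mouth to nose distance",
    D30 = "Left lateral mouth to nose distance",
    D31 = "Right median-sagittal mouth to nose distance",
    D32 = "Left median-sagittal mouth to nose distance")
  for (id in names(dist2))
    def[[id]] <- list(id = id, name = unname(dist_names[id]), kind = "distance",
                      inputs = dist2[[id]])
  perp <- list(D4 = list(point = "prn", line = c("n", "sn")),
               D16 = list(point = "sls", line = c("prl", "sn")),
               D27 = list(point = "lvR", line = c("chR", "cphR")),
               D28 = list(point = "lvL", line = c("chL", "cphL")))
  for (id in names(perp))
    def[[id]] <- list(id = id, name = unname(dist_names[id]),
                      kind = "perpendicular",
                      inputs = c(perp[[id]]$point, perp[[id]]$line),
                      point = perp[[id]]$point, line = perp[[id]]$line)

  curves <- list(
    S1 = list("Volumetric upper nasal height", c("n", "prn"), FALSE),
    S2 = list("Volumetric lower nasal height", c("prn", "sn"), FALSE),
    S3 = list("Volumetric nasal height", c("n", "prn", "sn"), FALSE),
    S4 = list("Volumetric soft-tissue nasal width right", c("acbR", "prn"), FALSE),
    S5 = list("Volumetric soft-tissue nasal width left", c("prn", "acbL"), FALSE),
    S6 = list("Right inner nostril circumference", c("cbR", "mabR", "aliR"), TRUE),
    S7 = list("Left inner nostril circumference", c("cbL", "mabL", "aliL"), TRUE),
    S8 = list("Right volumetric lateral columella length", c("cR", "cbR"), FALSE),
    S9 = list("Left volumetric lateral columella length", c("cL", "cbL"), FALSE),
    S10 = list("Right columellar base width", c("cbR", "sn"), FALSE),
    S11 = list("Left columellar base width", c("sn", "cbL"), FALSE),
    S12 = list("Columellar base width", c("cbR", "sn", "cbL"), FALSE),
    S13 = list("Volumetric philtrum length", c("sn", "ls"), FALSE),
    S14 = list("Philtrum base width (Volumetric)", c("cphR", "ls", "cphL"), FALSE),
    S15 = list("Medial vermillion height", c("ls", "vmjM", "sto"), FALSE),
    S16 = list("Right vermillion height", c("cphR", "vmjR", "sto"), FALSE),
    S17 = list("Left vermillion height", c("cphL", "vmjL", "sto"), FALSE),
    S18 = list("Volumetric upper lip height", c("sn", "ls", "sto"), FALSE),
    S19 = list("Right dry vermillion height", c("cphR", "vmjR"), FALSE),
    S20 = list("Median dry vermillion height", c("ls", "vmjM"), FALSE),
    S21 = list("Left dry vermillion height", c("cphL", "vmjL"), FALSE),
    S22 = list("Right wet vermillion height", c("vmjR", "sto"), FALSE),
    S23 = list("Median wet vermillion height", c("vmjM", "sto"), FALSE),
    S24 = list("Left wet vermillion height", c("vmjL", "sto"), FALSE),
    S25 = list("Right volumetric vermillion length", c("chR", "cphR", "ls"), FALSE),
    S26 = list("Left volumetric vermillion length", c("chL", "cphL", "ls"), FALSE),
    S27 = list("Vertical heights of the right medial lip (Philtrum, Volumetric)",
               c("cbR", "cphR"), FALSE),
    S28 = list("Vertical heights of the left medial lip (Philtrum, Volumetric)",
               c("cbL", "cphL"), FALSE),
    S29 = list("Right philtrum base width (Volumetric)", c("cphR", "ls"), FALSE),
    S30 = list("Left philtrum base width (Volumetric)", c("ls", "cphL"), FALSE),
    S31 = list("Right lateral volumetric vermillion length", c("chR", "cphR"), FALSE),
    S32 = list("Left lateral volumetric vermillion length", c("chL", "cphL"), FALSE))
  for (id in names(curves))
    def[[id]] <- list(id = id, name = curves[[id]][[1]], kind = "surface_curve",
                      inputs = curves[[id]][[2]], waypoints = curves[[id]][[2]],
                      closed = curves[[id]][[3]])

  def$A1 <- list(id = "A1", name = "Columellar angle", kind = "angle2dir",
                 inputs = c("cM", "sn", "chR", "chL"),
                 dir1 = c("cM", "sn"), dir2 = c("chR", "chL"))
  def$A2 <- list(id = "A2", name = "Vermillion angle", kind = "angle3",
                 inputs = c("chR", "ls", "chL"),
                 rays = c("chR", "chL"), vertex = "ls")

  idx <- list(
    I1 = list("Vertical nasal convexity index", num = "S3", den = "D1"),
    I2 = list("Alar convexity index", num = c("S4", "S5"), den = c("D5", "D6")),
    I3 = list("Right columella index", num = "S8", den = "D12"),
    I4 = list("Left columella index", num = "S9", den = "D13"),
    I5 = list("Columella index", num = c("S8", "S9"), den = c("D12", "D13")),
    I6 = list("Horizontal nasal convexity index", num = c("S4", "S5"), den = "D2"),
    I7 = list("Nasal convexity index", of = c("I1", "I6")),
    I8 = list("Columella base symetry index", num = "S10", den = "S11"),
    I9 = list("Dimple index", num = "S13", den = "D22"),
    I10 = list("Philtrum taper index", num = "S14", den = "S12"),
    I11 = list("Upper lip index", num = "S18", den = "D21"),
    I12 = list("Right vermillion index", num = "S25", den = "D23"),
    I13 = list("Left vermillion index", num = "S26", den = "D24"),
    I14 = list("Vermillion index", num = c("S25", "S26"), den = c("D23", "D24")),
    I15 = list("Lateral mouth to nose symetry index",
               num = c("D29", "D17"), den = c("D30", "D18")),
    I16 = list("Central mouth to nose symetry index",
               num = c("D19", "D31"), den = c("D20", "D32")),
    I17 = list("Mouth to nose symetry index", of = c("I15", "I16")),
    I18 = list("Soft-tissue mouth to nose index", num = "D15",
               den = c("D2", "D3"), den_rule = "max"))
  for (id in names(idx)) {
    e <- idx[[id]]
    inputs <- if (!is.null(e$of)) {
      unique(unlist(lapply(idx[e$of], function(z) c(z$num, z$den))))
    } else c(e$num, e$den)
    def[[id]] <- list(id = id, name = e[[1]], kind = "index", inputs = inputs,
                      num = e$num, den = e$den, of = e$of,
                      den_rule = if (is.null(e$den_rule)) "sum" else e$den_rule)
  }
  reg <- structure(def, class = "naso_registry")
  .registry_cache$reg <- reg
  reg
}

.registry_cache <- new.env(parent = emptyenv())

# Two-point distance definitions (the 28 direct D-parameters).
registry_distance_pairs <- function() {
  list(D1 = c("n", "sn"), D2 = c("acbR", "acbL"), D3 = c("alR", "alL"),
       D5 = c("acbR", "prn"), D6 = c("acbL", "prn"), D7 = c("aloR", "aliR"),
       D8 = c("aloL", "aliL"), D9 = c("sbalR", "sbalL"),
       D10 = c("mabR", "cbR"), D11 = c("mabL", "cbL"), D12 = c("cR", "cbR"),
       D13 = c("cL", "cbL"), D14 = c("cM", "sn"), D15 = c("chR", "chL"),
       D17 = c("sbalR", "cphR"), D18 = c("sbalL", "cphL"),
       D19 = c("cbR", "cphR"), D20 = c("cbL", "cphL"), D21 = c("sn", "sto"),
       D22 = c("sn", "ls"), D23 = c("chR", "ls"), D24 = c("chL", "ls"),
       D25 = c("chR", "cphR"), D26 = c("chL", "cphL"), D29 = c("chR", "acbR"),
       D30 = c("chL", "acbL"), D31 = c("ls", "cbR"), D32 = c("ls", "cbL"))
}

#' @export
print.naso_registry <- function(x, ...) {
  kinds <- vapply(x, `[[`, "", "kind")
  cat("<naso_registry> 84-parameter battery\n")
  print(table(kinds))
  invisible(x)
}

#' Export the registry as a data.frame (CSV/JSON-ready)
#' @param reg A `naso_registry` (default [registry()]).
#' @return Data.frame: id, name, kind, inputs (comma-separated), formula.
#' @export
registry_table <- function(reg = registry()) {
  data.frame(
    id = names(reg),
    name = vapply(reg, `[[`, "", "name"),
    kind = vapply(reg, `[[`, "", "kind"),
    inputs = vapply(reg, function(e) paste(e$inputs, collapse = ","), ""),
    formula = vapply(reg, function(e) {
      if (e$kind == "index") {
        if (!is.null(e$of)) paste0("(", paste(e$of, collapse = "+"), ")/2")
        else paste0("(", paste(e$num, collapse = "+"), ")/",
                    if (e$den_rule == "max") paste0("max(", paste(e$den, collapse = ","), ")")
                    else paste0("(", paste(e$den, collapse = "+"), ")"))
      } else if (e$kind == "surface_curve") {
        paste0(paste(e$waypoints, collapse = "-"), if (e$closed) " (closed)" else "")
      } else if (e$kind == "perpendicular") {
        paste0("perp(", e$point, "; ", paste(e$line, collapse = "-"), ")")
      } else paste(e$inputs, collapse = "-")
    }, ""),
    row.names = NULL, stringsAsFactors = FALSE)
}
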