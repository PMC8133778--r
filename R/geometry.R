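#' Assay geometry
#'
#' Describes the arena of one of the three assays: the elevated plus maze
#' (EPM), the rat-exposure arena (RAT) and its toy-rat control (TOY, same box
#' as RAT but with an inanimate stimulus).
#'
#' EPM coordinates are centered on the maze center with open arms along x and
#' closed arms along y; each arm is 30 cm long and 7 cm wide, with a 7 x 7 cm
#' center square. The rat arena is a 70 x 26 cm box with origin at the
#' safe-wall corner; the rat is tethered at the wall opposite the safe zone
#' (the left 20% of the arena by x position), and positions within 14 cm of
#' the rat count as threatening.
#'
#' @param assay_kind one of "EPM", "RAT", "TOY".
#' @param arm_length,arm_width EPM arm dimensions, cm.
#' @param arena_length,arena_width rat-arena dimensions, cm.
#' @param safe_zone_fraction fraction of arena length forming the safe zone.
#' @param threat_radius_cm distance to the rat defining the threatening zone.
#' @return An object of class `assay_geometry`.
#' @export
assay_geometry <- function(assay_kind = c("EPM", "RAT", "TOY"),
                           arm_length = 30, arm_width = 7,
                           arena_length = 70, arena_width = 26,
                           safe_zone_fraction = 0.2, threat_radius_cm = 14) {
  assay_kind <- match.arg(assay_kind)
  stopifnot(arm_length > 0, arm_width > 0, arena_length > 0, arena_width > 0,
            safe_zone_fraction > 0, safe_zone_fraction < 1, threat_radius_cm > 0)
  structure(list(assay_kind = assay_kind, arm_length = arm_length,
                 arm_width = arm_width, arena_length = arena_length,
                 arena_width = arena_width,
                 safe_zone_fraction = safe_zone_fraction,
                 threat_radius_cm = threat_radius_cm),
            class = "assay_geometry")
}

#' @export
print.assay_geometry <- function(x, ...) {
  if (x$assay_kind == "EPM")
    cat(sprintf("<assay_geometry> EPM: 4 arms %g x %g cm + center square\n",
                x$arm_length, x$arm_width))
  else
    cat(sprintf("<assay_geometry> %s arena %g x %g cm (safe zone left %g%%)\n",
                x$assay_kind, x$arena_length, x$arena_width,
                100 * x$safe_zone_fraction))
  invisible(x)
}

# Half-extent of the EPM along either axis: arm length + half center square.
#' @noRd
epm_half_extent <- function(geometry) geometry$arm_length + geometry$arm_width / 2

# Rat tether point: middle of the wall opposite the safe zone.
#' @noRd
rat_home <- function(geometry) c(geometry$arena_length, geometry$arena_width / 2)
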