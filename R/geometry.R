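#' Aorta segment table
#'
#' Returns the default human-scale aortic geometry used by the simulator: the
#' ascending aorta, aortic arch, thoracic and abdominal aorta with the iliac
#' continuation, and the major branches (brachiocephalic with right
#' subclavian continuation, left subclavian, coronary, renal). Segment
#' lengths and inlet diameters follow the mold dimensions of a one-to-one
#' human aorta replica.
#'
#' Each row is one segment. `attach_after` names the segment at whose distal
#' junction this segment connects (`NA` for the root segment); `terminal`
#' marks segments whose distal end carries an outlet unit (syringe compliance
#' plus clamp resistance). `n_compartments` controls the ladder subdivision;
#' the default gives compartments of roughly 10 mm so the ladder supports a
#' finite wave-transit time.
#'
#' @param compartment_length_mm Target compartment length for the subdivision
#'   (mm). Each segment gets `ceiling(length / compartment_length_mm)`
#'   compartments, at least one.
#' @return A data.frame with columns `name`, `length_mm`, `inlet_diameter_mm`,
#'   `n_compartments`, `terminal`, `attach_after`.
#' @export
#' @examples
#' aorta_segments()
aorta_segments <- function(compartment_length_mm = 10) {
  seg <- data.frame(
    name = c("ascending_aorta", "aortic_arch", "thoracic_aorta",
             "abdominal_aorta", "iliac_artery", "coronary_artery",
             "brachiocephalic_artery", "right_subclavian_artery",
             "left_subclavian_artery", "renal_artery"),
    length_mm = c(70, 60, 170, 130, 76, 45, 34, 65, 100, 65),
    inlet_diameter_mm = c(24.0, 18.0, 20.0, 16.0, 12.0, 4.0, 12.4, 8.4, 8.4, 5.0),
    terminal = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    attach_after = c(NA, "ascending_aorta", "aortic_arch", "thoracic_aorta",
                     "abdominal_aorta", "ascending_aorta", "aortic_arch",
                     "brachiocephalic_artery", "aortic_arch", "abdominal_aorta"),
    stringsAsFactors = FALSE
  )
  seg$n_compartments <- pmax(1L, as.integer(ceiling(seg$length_mm / compartment_length_mm)))
  seg
}

validate_segments <- function(geometry) {
  if (!is.data.frame(geometry) || nrow(geometry) == 0)
    stop("geometry must be a nonempty data.frame of aorta segments", call. = FALSE)
  need <- c("name", "length_mm", "inlet_diameter_mm", "terminal", "attach_after")
  miss <- setdiff(need, names(geometry))
  if (length(miss))
    stop("geometry is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(geometry$n_compartments))
    geometry$n_compartments <- pmax(1L, as.integer(ceiling(geometry$length_mm / 10)))
  if (any(geometry$length_mm <= 0) || any(geometry$inlet_diameter_mm <= 0))
    stop("segment lengths and diameters must be positive", call. = FALSE)
  if (any(geometry$n_compartments < 1))
    stop("each segment needs at least one compartment", call. = FALSE)
  if (anyDuplicated(geometry$name))
    stop("segment names must be unique", call. = FALSE)
  if (sum(is.na(geometry$attach_after)) != 1)
    stop("exactly one root segment (attach_after = NA) is required", call. = FALSE)
  known <- geometry$name
  bad <- setdiff(stats::na.omit(geometry$attach_after), known)
  if (length(bad))
    stop("attach_after refers to unknown segments: ", paste(bad, collapse = ", "),
         call. = FALSE)
  # every leaf (segment nobody attaches to) must be terminal
  leaves <- setdiff(known, geometry$attach_after)
  not_term <- leaves[!geometry$terminal[match(leaves, known)]]
  if (length(not_term))
    stop("leaf segments must be terminal: ", paste(not_term, collapse = ", "),
         call. = FALSE)
  geometry
}
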