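# The 60-electrode 10-20 montage used throughout: labels in acquisition
# order plus a flat 2-D scalp projection. The projection is only used to
# compute mixing-weight decay in the simulator; its exact geometry is
# irrelevant as long as electrodes of the same functional region are
# mutually nearest.

.MONTAGE_LABELS <- c(
  "Fp1", "Fpz", "Fp2", "AF7", "AF3", "AF4", "AF8",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
  "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
  "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
  "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
  "PO7", "PO3", "POz", "PO4", "PO8",
  "O1", "Oz", "O2"
)

.ROW_Y <- c(Fp = 4, AF = 3, F = 2, FT = 1, FC = 1, T = 0, C = 0,
            TP = -1, CP = -1, P = -2, PO = -3, O = -4)

# anterior-posterior row and left-right column from the 10-20 label:
# trailing "z" -> midline (x = 0); odd digit n -> left at -(n+1)/2;
# even digit n -> right at n/2.
.labelCoord <- function(label) {
  suffix <- sub("^[A-Za-z]*?([0-9]+|z)$", "\\1", label)
  prefix <- sub("([0-9]+|z)$", "", label)
  y <- .ROW_Y[[prefix]]
  x <- if (suffix == "z") 0 else {
    n <- as.integer(suffix)
    if (n %% 2 == 1) -(n + 1) / 2 else n / 2
  }
  c(x = x, y = y)
}

#' The 60-channel 10-20 montage
#'
#' Returns the 60 electrode labels of the recording montage in acquisition
#' order, together with a schematic 2-D scalp projection (columns `x`, `y`)
#' used by the simulator to compute distance-dependent mixing weights.
#'
#' @return data.frame with columns `label`, `x`, `y` (60 rows).
#' @examples
#' m <- makeMontage()
#' nrow(m)           # 60
#' m$label[1]        # "Fp1"
#' @export
makeMontage <- function() {
  xy <- t(vapply(.MONTAGE_LABELS, .labelCoord, c(x = 0, y = 0)))
  data.frame(label = .MONTAGE_LABELS, x = xy[, "x"], y = xy[, "y"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' The seven mental-task labels
#'
#' Silence (S), left hand (LH), right hand (RH), left foot (LF), and the
#' compound tasks LH&RH, LH&LF, RH&LF.
#'
#' @return character vector of length 7.
#' @export
taskLabels <- function() {
  c("S", "LH", "RH", "LF", "LH&RH", "LH&LF", "RH&LF")
}

#' Default task-to-region activation map
#'
#' Which region centres (C3, C4, Cz) are active for each task: hand tasks
#' activate the contralateral hand area (LH -> C4, RH -> C3), foot tasks
#' the midline foot area (LF -> Cz), compound tasks the union, and silence
#' none.
#'
#' @return named list over [taskLabels()].
#' @export
defaultTaskRegionMap <- function() {
  list(
    "S" = character(0),
    "LH" = "C4",
    "RH" = "C3",
    "LF" = "Cz",
    "LH&RH" = c("C3", "C4"),
    "LH&LF" = c("C4", "Cz"),
    "RH&LF" = c("C3", "Cz")
  )
}

.REGION_NODES <- list(
  C3 = c("F1", "F3", "F5", "FC1", "FC3", "FC5", "C1", "C3", "C5",
         "CP1", "CP3", "CP5", "P1", "P3", "P5"),
  C4 = c("F2", "F4", "F6", "FC2", "FC4", "FC6", "C2", "C4", "C6",
         "CP2", "CP4", "CP6", "P2", "P4", "P6"),
  Cz = c("F1", "F2", "Fz", "FC1", "FC2", "FCz", "C1", "C2", "Cz",
         "CP1", "CP2", "CPz", "P1", "P2", "Pz")
)

#' Regional 15-electrode node sets
#'
#' The fixed node sets of the three regional brain functional networks
#' centred on C3 (left hand area), C4 (right hand area) and Cz (foot
#' area): 15 electrodes each, spanning the frontal-to-parietal strip over
#' the corresponding motor cortex.
#'
#' @param name region name, one of `"C3"`, `"C4"`, `"Cz"`.
#' @return character vector of 15 electrode labels; the region centre is
#'   attached as attribute `"center"`.
#' @examples
#' regionNodes("C3")
#' @export
regionNodes <- function(name) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% names(.REGION_NODES))
    stop("unknown region '", paste(name, collapse = ","),
         "'; must be one of C3, C4, Cz")
  nodes <- .REGION_NODES[[name]]
  attr(nodes, "center") <- name
  nodes
}
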