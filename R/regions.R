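#' Cerebral region names of the 90-region anatomical parcellation
#'
#' Ordered names of the 90 cerebral regions (cerebellum excluded) of the
#' Automated Anatomical Labeling atlas, in the conventional label order
#' (odd indices left hemisphere, even indices right). These are the network
#' nodes used throughout the package and the default column names of
#' synthetic SUV matrices.
#'
#' @return Character vector of length 90.
#' @export
#' @examples
#' head(aal90_regions())
aal90_regions <- function() {
  stems <- c(
    "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
    "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
    "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
    "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
    "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
    "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
    "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
    "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
    "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
    "Pallidum", "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
    "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf"
  )
  as.vector(t(outer(stems, c("L", "R"), paste, sep = "_")))
}

#' Resolve a region name to its column index
#'
#' @param region Region name (e.g. `"Postcentral_R"`).
#' @param region_names Character vector of valid region names.
#' @return Integer index of `region` within `region_names`.
#' @export
match_region <- function(region, region_names = aal90_regions()) {
  stopifnot(is.character(region), length(region) == 1L)
  idx <- match(region, region_names)
  if (is.na(idx)) {
    stop("Unknown region name '", region, "'. Valid names include: ",
         paste(utils::head(region_names, 6), collapse = ", "), ", ...",
         call. = FALSE)
  }
  idx
}
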