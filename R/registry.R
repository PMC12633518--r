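# ROI registry: the fixed 87-region parcellation all analyses index against.

.DK_CORTICAL <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
  "temporalpole", "transversetemporal", "insula"
)

.SUBCORTICAL <- c(
  "thalamus", "caudate", "putamen", "pallidum",
  "hippocampus", "amygdala", "accumbens", "ventraldc"
)

#' Build the default 87-region parcellation registry
#'
#' The registry fixes the canonical region order used by every downstream
#' analysis: left cortical (34 Desikan-Killiany regions), right cortical,
#' left subcortical (8 regions), right subcortical, left and right
#' cerebellar cortex, brainstem. Edge indices of similarity matrices are
#' always derived from this order, never from input file order.
#'
#' @return A `roi_registry`: a data.frame with columns `name`, `hemisphere`
#'   (`"L"`, `"R"` or `"midline"`), `class` (`"cortical"`, `"subcortical"`,
#'   `"cerebellar"`, `"brainstem"`) and `base` (hemisphere-stripped name,
#'   identifying homologous pairs).
#' @export
#' @examples
#' reg <- build_default_registry()
#' nrow(reg)                      # 87
#' table(reg$class)
build_default_registry <- function() {
  entry <- function(name, hemi, cls, base) {
    data.frame(name = name, hemisphere = hemi, class = cls, base = base,
               stringsAsFactors = FALSE)
  }
  reg <- rbind(
    entry(paste0("L_", .DK_CORTICAL), "L", "cortical", .DK_CORTICAL),
    entry(paste0("R_", .DK_CORTICAL), "R", "cortical", .DK_CORTICAL),
    entry(paste0("L_", .SUBCORTICAL), "L", "subcortical", .SUBCORTICAL),
    entry(paste0("R_", .SUBCORTICAL), "R", "subcortical", .SUBCORTICAL),
    entry("L_cerebellum_cortex", "L", "cerebellar", "cerebellum_cortex"),
    entry("R_cerebellum_cortex", "R", "cerebellar", "cerebellum_cortex"),
    entry("brainstem", "midline", "brainstem", "brainstem")
  )
  stopifnot(!anyDuplicated(reg$name))
  class(reg) <- c("roi_registry", "data.frame")
  reg
}

#' Homologous left/right region pairs of a registry
#'
#' @param registry a `roi_registry`
#' @return data.frame with columns `left`, `right` (region names), one row
#'   per homologous pair; midline regions are excluded.
#' @export
roi_pairs <- function(registry) {
  lh <- registry[registry$hemisphere == "L", ]
  rh <- registry[registry$hemisphere == "R", ]
  common <- intersect(lh$base, rh$base)
  data.frame(
    left = lh$name[match(common, lh$base)],
    right = rh$name[match(common, rh$base)],
    stringsAsFactors = FALSE
  )
}

#' Reduced registry for fast simulation studies
#'
#' Subsets the default registry while preserving canonical order; handy for
#' property tests and power simulations where the full 87-region network is
#' unnecessarily slow.
#'
#' @param n_regions number of regions to keep (head of the canonical order)
#' @return a `roi_registry` with `n_regions` rows
#' @export
subset_registry <- function(n_regions) {
  reg <- build_default_registry()
  if (n_regions < 2 || n_regions > nrow(reg)) {
    stop("n_regions must be in [2, ", nrow(reg), "]")
  }
  out <- reg[seq_len(n_regions), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("roi_registry", "data.frame")
  out
}
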