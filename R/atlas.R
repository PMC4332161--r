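# 34 bilateral cortical parcels of the Desikan-Killiany atlas.
dk_base_names <- c(
  "banks of the superior temporal sulcus",
  "caudal anterior cingulate",
  "caudal middle frontal",
  "cuneus",
  "entorhinal",
  "frontal pole",
  "fusiform",
  "inferior parietal",
  "inferior temporal",
  "insula",
  "isthmus of the cingulate",
  "lateral occipital",
  "lateral orbitofrontal",
  "lingual",
  "medial orbitofrontal",
  "middle temporal",
  "parahippocampal",
  "paracentral",
  "pars opercularis",
  "pars orbitalis",
  "pars triangularis",
  "peri-calcarine",
  "postcentral",
  "posterior cingulate",
  "precentral",
  "precuneus",
  "rostral anterior cingulate",
  "rostral middle frontal",
  "superior frontal",
  "superior parietal",
  "superior temporal",
  "supra-marginal",
  "temporal pole",
  "transverse temporal"
)

#' Bilateral Desikan-Killiany cortical region atlas
#'
#' Returns the fixed, ordered list of the 68 cortical regions used as
#' network nodes: the 34 Desikan-Killiany parcels of the left hemisphere
#' followed by the same 34 parcels of the right hemisphere.
#'
#' @return Character vector of length 68. Each label is of the form
#'   `"Left <region>"` or `"Right <region>"`; the left-hemisphere block
#'   comes first and the order is deterministic.
#'
#' @examples
#' atlas <- region_atlas()
#' length(atlas)
#' atlas[c(27, 54)]
#' @export
region_atlas <- function() {
  c(paste("Left", dk_base_names), paste("Right", dk_base_names))
}

# Node labels for a graph of arbitrary size: the real atlas when n == 68,
# generic numbered labels otherwise (used by reduced-size simulations).
node_labels <- function(n_nodes) {
  if (n_nodes == 68L) region_atlas() else sprintf("region_%02d", seq_len(n_nodes))
}
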