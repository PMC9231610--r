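#' Neocortical cell subclass taxonomy
#'
#' The 19-subclass reference taxonomy used throughout the package: five
#' GABAergic interneuron subclasses (named by marker genes), seven
#' glutamatergic projection-neuron subclasses (named by layer and projection
#' target), and seven non-neuronal subclasses. Subclass is the intermediate
#' taxonomic resolution between class (e.g., inhibitory) and fine type
#' (e.g., Martinotti cell).
#'
#' @return A data frame with columns `subclass` (character, 19 unique labels)
#'   and `class` (factor with levels GABAergic, glutamatergic, non-neuronal).
#' @export
#' @examples
#' tax <- cortical_taxonomy()
#' table(tax$class)
cortical_taxonomy <- function() {
  gaba <- c("LAMP5", "PAX6", "SST", "VIP", "PVALB")
  glut <- c("IT", "L4 IT", "L5 6 IT Car3", "L5 6 NP", "L5 ET", "L6 CT", "L6b")
  nonn <- c("Astrocyte", "Oligodendrocyte", "OPC", "Microglia",
            "Endothelial", "Pericyte", "VLMC")
  data.frame(
    subclass = c(gaba, glut, nonn),
    class = factor(rep(c("GABAergic", "glutamatergic", "non-neuronal"),
                       c(length(gaba), length(glut), length(nonn))),
                   levels = c("GABAergic", "glutamatergic", "non-neuronal")),
    stringsAsFactors = FALSE
  )
}

#' Validate a taxonomy table
#'
#' @param taxonomy A data frame as returned by [cortical_taxonomy()].
#' @return Invisibly, the taxonomy. Errors if labels are duplicated or a
#'   class label is unknown.
#' @export
validate_taxonomy <- function(taxonomy) {
  stopifnot(is.data.frame(taxonomy),
            all(c("subclass", "class") %in% names(taxonomy)))
  if (anyDuplicated(taxonomy$subclass))
    stop("duplicated subclass labels in taxonomy")
  if (!all(as.character(taxonomy$class) %in%
           c("GABAergic", "glutamatergic", "non-neuronal")))
    stop("unknown class labels in taxonomy")
  invisible(taxonomy)
}
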