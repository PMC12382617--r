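#' Load the degradation-pathway energetics ledger
#'
#' The ledger bundles the DFT-derived (PBE/L1) C-H bond dissociation
#' energies of tetracycline by carbon position, the catalogue of identified
#' degradation products, and the transformation pathways with their
#' direct/indirect ionization-event counts. The file is validated on load:
#' reaction types must come from the known vocabulary, event counts must be
#' non-negative with at least one positive count per step, and the energy
#' table must be finite and positive.
#'
#' @param path JSON ledger path; defaults to the bundled tetracycline ledger
#' @return an object of class \code{pathway_ledger}: list with \code{parent},
#'   \code{bde} (tibble position/dE/dG), \code{energy_notes}, and
#'   \code{pathways} (list of pathway records, each with a \code{steps}
#'   tibble)
#' @export
load_pathway_ledger <- function(path = system.file(
                                  "extdata", "tetracycline_pathways.json",
                                  package = "ebikin")) {
  if (!file.exists(path)) stop("ledger file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  reaction_types <- c("hydroxylation", "demethylation", "deaminomethylation",
                      "dehydroxylation", "H-elimination", "H-addition",
                      "amination", "methyl-elimination")
  bde <- tibble::tibble(position = raw$bde$positions,
                        dE_kcal_mol = raw$bde$dE_kcal_mol,
                        dG_kcal_mol = raw$bde$dG_kcal_mol)
  if (anyNA(bde$dE_kcal_mol) || anyNA(bde$dG_kcal_mol) ||
      any(bde$dE_kcal_mol <= 0) || any(bde$dG_kcal_mol <= 0)) {
    stop("ledger schema violation: bond energies must be finite and positive",
         call. = FALSE)
  }
  pw <- raw$pathways
  pathways <- lapply(seq_len(nrow(pw)), function(i) {
    steps <- tibble::as_tibble(pw$steps[[i]])
    if (nrow(steps) == 0L) {
      stop("ledger schema violation: pathway ", pw$product[i],
           " has no steps", call. = FALSE)
    }
    bad_type <- setdiff(steps$reaction, reaction_types)
    if (length(bad_type) > 0L) {
      stop("ledger schema violation: unknown reaction type ",
           paste(bad_type, collapse = ", "), call. = FALSE)
    }
    if (any(steps$direct < 0) || any(steps$indirect < 0) ||
        any(steps$direct + steps$indirect == 0)) {
      stop("ledger schema violation: each step needs non-negative counts ",
           "with at least one positive", call. = FALSE)
    }
    list(product = pw$product[i], mz = pw$mz[i],
         table_dose_kGy = pw$table_dose_kGy[i],
         text_dose_kGy = pw$text_dose_kGy[i],
         fitted_D0_kGy = pw$fitted_D0_kGy[i],
         uncertain = pw$uncertain[i],
         net_energy_kcal_mol = pw$net_energy_kcal_mol[i],
         steps = steps)
  })
  names(pathways) <- pw$product
  structure(list(parent = raw$parent, parent_mz = raw$parent_mz,
                 bde = bde, energy_notes = raw$energy_notes,
                 pathways = pathways),
            class = "pathway_ledger")
}

#' Load the degradation-product catalogue
#'
#' Accurate masses, molecular formulas, retention times and detection doses
#' of the degradation products identified after electron-beam irradiation,
#' keyed by parent antibiotic.
#'
#' @param path CSV path; defaults to the bundled catalogue
#' @return a tibble of species records
#' @export
load_species_catalogue <- function(path = system.file(
                                     "extdata", "degradation_products.csv",
                                     package = "ebikin")) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (any(x$mz <= 0)) stop("species catalogue: m/z must be positive",
                           call. = FALSE)
  if (!all(x$dose_kGy %in% c(0.1, 1, 3, 7))) {
    stop("species catalogue: detection dose must be one of 0.1, 1, 3, 7 kGy",
         call. = FALSE)
  }
  tibble::as_tibble(x)
}

#' Reaction energy change
#'
#' Products-minus-reactants energy difference; negative means energy is
#' released. Antisymmetric under swapping the arguments.
#'
#' @param products_energy total energy of the products, kcal/mol
#' @param reactants_energy total energy of the reactants, kcal/mol
#' @return energy change in kcal/mol
#' @export
reaction_energy <- function(products_energy, reactants_energy) {
  stopifnot(is.finite(products_energy), is.finite(reactants_energy))
  products_energy - reactants_energy
}

#' Most weakly bound hydrogen position
#'
#' Returns the carbon position with the smallest C-H bond dissociation
#' energy (total energy dE or Gibbs energy dG), i.e. the site most prone to
#' radical attack. Ties break deterministically towards the earlier
#' position in the table's order.
#'
#' @param bde bond-energy tibble (columns \code{position},
#'   \code{dE_kcal_mol}, \code{dG_kcal_mol}), e.g.
#'   \code{load_pathway_ledger()$bde}
#' @param which \code{"dE"} or \code{"dG"}
#' @return list with \code{position} and \code{energy} (kcal/mol)
#' @export
min_energy_site <- function(bde, which = c("dE", "dG")) {
  which <- match.arg(which)
  if (nrow(bde) == 0L) stop("empty bond-energy table", call. = FALSE)
  col <- paste0(which, "_kcal_mol")
  i <- which.min(bde[[col]])
  list(position = bde$position[i], energy = bde[[col]][i])
}

#' Count ionization events along a degradation pathway
#'
#' Sums the direct (primary-electron) and indirect (radiolysis-radical)
#' ionization events over the pathway's transformation steps. Fewer events
#' means the product forms at lower dose and makes a better degradation
#' marker.
#'
#' @param pathway a pathway record from \code{\link{load_pathway_ledger}}
#' @return list with \code{direct}, \code{indirect}, \code{total}
#' @export
count_ionization_events <- function(pathway) {
  steps <- pathway$steps
  if (is.null(steps) || nrow(steps) == 0L) {
    stop("pathway has no transformation steps", call. = FALSE)
  }
  direct <- sum(steps$direct)
  indirect <- sum(steps$indirect)
  list(direct = direct, indirect = indirect, total = direct + indirect)
}

#' Rank degradation products as candidate markers
#'
#' Orders products ascending by total ionization events, then by detection
#' dose, then by fitted threshold dose D0; products needing the fewest
#' ionization events appear at the lowest doses and are the most reliable
#' markers for reconstructing the initial contamination. The ranking is a
#' deterministic total order: permuting the input leaves it unchanged
#' (remaining ties break alphabetically by product name).
#'
#' @param ledger a \code{pathway_ledger}, or a list of pathway records
#' @return a tibble with one row per product, ordered by rank, with columns
#'   \code{rank}, \code{product}, \code{mz}, \code{direct}, \code{indirect},
#'   \code{total_events}, \code{detection_dose_kGy}, \code{fitted_D0_kGy},
#'   \code{uncertain}
#' @export
rank_markers <- function(ledger) {
  pathways <- if (inherits(ledger, "pathway_ledger")) ledger$pathways else ledger
  if (length(pathways) == 0L) stop("no products to rank", call. = FALSE)
  rows <- lapply(pathways, function(p) {
    ev <- count_ionization_events(p)
    tibble::tibble(product = p$product, mz = p$mz,
                   direct = ev$direct, indirect = ev$indirect,
                   total_events = ev$total,
                   detection_dose_kGy = p$table_dose_kGy,
                   fitted_D0_kGy = if (is.null(p$fitted_D0_kGy)) NA_real_
                                   else p$fitted_D0_kGy,
                   uncertain = isTRUE(p$uncertain))
  })
  out <- do.call(rbind, rows)
  ord <- order(out$total_events, out$detection_dose_kGy, out$fitted_D0_kGy,
               out$product)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out[, c("rank", setdiff(names(out), "rank"))]
}
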