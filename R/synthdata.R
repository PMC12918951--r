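# Synthetic structure-activity data with a planted pharmacophore.
#
# Molecules are assembled from a fragment grammar (aromatic/aliphatic
# scaffold templates x substituent sets), which guarantees chemical validity
# without a valence-repair pass. Activity is driven by a planted
# nitrogen-containing fused-aromatic motif (a quinoline core) plus Bernoulli
# label noise; binary target annotations contain one "hub" annotation that is
# strongly enriched among actives, the rest are class-independent background.

MOTIF_SMARTS_DEFAULT <- "c1ccc2ncccc2c1"

# Scaffold templates; "{1}"/"{2}" are optional substitution slots on carbon.
MOTIF_TEMPLATES <- c(
  "c1c{1}cc2ncc{2}cc2c1",        # quinoline, substituents on both rings
  "c1cc2ncc{1}cc2cc1{2}",        # quinoline, alternative positions
  "c1c{1}c{2}c2ncccc2c1"         # quinoline, benzo-ring substitution
)

PLAIN_TEMPLATES <- c(
  "c1c{1}cc{2}cc1",              # benzene
  "c1c{1}cnc{2}c1",              # pyridine (lone aromatic N, unfused)
  "c1c{1}cc2cc{2}ccc2c1",        # naphthalene
  "C1C{1}CCC{2}C1",              # cyclohexane
  "c1c{1}oc(c1){2}",             # furan
  "c1c{1}cc(cc1)C1CC{2}CC1",     # phenyl-cyclopentane
  "C1CC{1}N(CC1)C(=O){2}"        # N-acyl piperidine
)

SUBSTITUENTS <- c("C", "CC", "C(C)C", "O", "OC", "N", "F", "Cl", "Br",
                  "C#N", "C(F)(F)F", "C(=O)O", "C(=O)N", "OCC", "S(=O)(=O)N",
                  "CO", "CN", "C(=O)C")

#' Synthetic-data generator configuration
#'
#' Defaults emulate a curated structure-activity corpus with substantial
#' class imbalance: 10.6% actives overall, activity driven by the planted
#' motif (`P(active | motif) = 0.9`, `P(active | no motif) = 0.02`), and 50
#' sparse binary target annotations of which one hub annotation appears for
#' 30% of actives but only 3.4% of inactives.
#'
#' @param n number of compounds.
#' @param active_fraction target overall active rate (default 0.106).
#' @param p_active_motif,p_active_nomotif label model (defaults 0.9 / 0.02).
#' @param motif_smarts planted pharmacophore (default: quinoline core).
#' @param n_targets number of annotation ids including the hub (default 50).
#' @param hub_rate_active,hub_rate_inactive class-conditional hub annotation
#'   rates (defaults 0.30 / 0.034).
#' @param background_rate per-target annotation rate for non-hub targets,
#'   independent of class (default 0.03).
#' @param p_substituent probability that a scaffold slot carries a
#'   substituent (default 0.7).
#' @param seed integer seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n = 2000L, active_fraction = 0.106,
                         p_active_motif = 0.9, p_active_nomotif = 0.02,
                         motif_smarts = MOTIF_SMARTS_DEFAULT,
                         n_targets = 50L, hub_rate_active = 0.30,
                         hub_rate_inactive = 0.034, background_rate = 0.03,
                         p_substituent = 0.7, seed = 1L) {
  probs <- c(active_fraction, p_active_motif, p_active_nomotif,
             hub_rate_active, hub_rate_inactive, background_rate,
             p_substituent)
  stopifnot(all(probs >= 0 & probs <= 1), n > 0, n_targets >= 1L)
  q <- (active_fraction - p_active_nomotif) /
    (p_active_motif - p_active_nomotif)
  if (!is.finite(q) || q <= 0 || q >= 1) {
    stop(sprintf(paste0("Infeasible generator config: required motif ",
                        "prevalence solves to %.3f, outside (0, 1)"), q),
         call. = FALSE)
  }
  structure(list(n = as.integer(n), active_fraction = active_fraction,
                 p_active_motif = p_active_motif,
                 p_active_nomotif = p_active_nomotif,
                 motif_smarts = motif_smarts, motif_prevalence = q,
                 n_targets = as.integer(n_targets),
                 hub_rate_active = hub_rate_active,
                 hub_rate_inactive = hub_rate_inactive,
                 background_rate = background_rate,
                 p_substituent = p_substituent, seed = as.integer(seed)),
            class = "synth_config")
}

with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

fill_template <- function(template, p_substituent) {
  for (slot in c("{1}", "{2}")) {
    sub <- if (stats::runif(1) < p_substituent) {
      paste0("(", sample(SUBSTITUENTS, 1L), ")")
    } else ""
    template <- sub(slot, sub, template, fixed = TRUE)
  }
  template
}

#' Generate synthetic molecules
#'
#' Draws motif presence at the solved prevalence, picks a scaffold template
#' accordingly, decorates the substitution slots, and standardizes the
#' result. All emitted SMILES are valid and survive standardization.
#'
#' @param config a [synth_config()].
#' @return a `compound_set` (unlabeled) with an additional logical column
#'   `motif` recording the planted-motif arm of the grammar.
#' @export
generate_molecules <- function(config) {
  with_preserved_seed(config$seed, {
    has_motif <- stats::runif(config$n) < config$motif_prevalence
    smi <- vapply(seq_len(config$n), function(k) {
      tmpl <- if (has_motif[k]) sample(MOTIF_TEMPLATES, 1L)
              else sample(PLAIN_TEMPLATES, 1L)
      fill_template(tmpl, config$p_substituent)
    }, character(1))
    ids <- sprintf("SYN%05d", seq_len(config$n))
    records <- make_compound_set(ids, smi)
    if (nrow(rejects(records)) > 0L) {
      stop("Fragment grammar emitted unstandardizable SMILES: ",
           paste(utils::head(rejects(records)$smiles_raw, 3), collapse = ", "),
           call. = FALSE)
    }
    records$motif <- has_motif
    records
  })
}

#' Assign activity labels from the motif model
#'
#' Bernoulli labels with `P(active | motif status)` from the configuration;
#' motif status is established by substructure match against the planted
#' SMARTS, so the label model sees exactly what a structure-based method can
#' recover.
#'
#' @param records a `compound_set` from [generate_molecules()].
#' @param config a [synth_config()].
#' @return `records` with the `label` column filled.
#' @export
assign_labels <- function(records, config) {
  sdfinfo <- ob_sdfset(records$smiles_std)
  counts <- ob_smarts_count(sdfinfo, config$motif_smarts,
                            nrow(records))
  matched <- !is.na(counts) & counts > 0
  with_preserved_seed(config$seed + 1L, {
    p <- ifelse(matched, config$p_active_motif, config$p_active_nomotif)
    records$label <- as.integer(stats::runif(nrow(records)) < p)
  })
  records$motif_matched <- matched
  records
}

#' Assign sparse binary target annotations
#'
#' The hub annotation is drawn at the class-conditional rates; the remaining
#' targets are class-independent background noise.
#'
#' @param records a labelled `compound_set`.
#' @param config a [synth_config()].
#' @return `records` with the `targets` list-column filled (hub id `T_HUB`,
#'   background ids `T002`...).
#' @export
assign_annotations <- function(records, config) {
  n <- nrow(records)
  bg_ids <- sprintf("T%03d", seq_len(config$n_targets - 1L) + 1L)
  with_preserved_seed(config$seed + 2L, {
    hub_p <- ifelse(records$label == 1, config$hub_rate_active,
                    config$hub_rate_inactive)
    hub <- stats::runif(n) < hub_p
    targets <- vector("list", n)
    for (k in seq_len(n)) {
      bg <- bg_ids[stats::runif(length(bg_ids)) < config$background_rate]
      targets[[k]] <- c(if (hub[k]) "T_HUB", bg)
    }
    records$targets <- targets
  })
  records
}

#' Generate a complete synthetic structure-activity dataset
#'
#' Molecules, labels and annotations in one call.
#'
#' @param config a [synth_config()].
#' @return a labelled, annotated `compound_set`.
#' @export
generate_dataset <- function(config = synth_config()) {
  records <- generate_molecules(config)
  records <- assign_labels(records, config)
  assign_annotations(records, config)
}

#' Generate a synthetic screening library with filter annotations
#'
#' Same grammar as [generate_dataset()] but unlabeled, with the annotation
#' columns consumed by the screening filter cascade (blood-brain-barrier
#' permeability and prior-testing flags).
#'
#' @param config a [synth_config()].
#' @param p_bbb,p_prior annotation rates for the two flags.
#' @return list with `records` (a `compound_set`) and `annotations`
#'   (data.frame with `id`, `bbb`, `prior_tested`).
#' @export
generate_screening_library <- function(config = synth_config(), p_bbb = 0.7,
                                       p_prior = 0.1) {
  records <- generate_molecules(config)
  ann <- with_preserved_seed(config$seed + 3L, {
    data.frame(id = records$id,
               bbb = stats::runif(nrow(records)) < p_bbb,
               prior_tested = stats::runif(nrow(records)) < p_prior)
  })
  list(records = records, annotations = ann)
}
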