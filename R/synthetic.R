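# Synthetic inputs with known ground truth. A small fragment grammar (~40
# ring systems, linkers and decorating groups) assembles valid SMILES by
# chain concatenation; ring-closure digits are assigned at assembly so
# fragments never collide. An "active substructure" fragment (an acyl
# piperidine amide, chosen to resemble the alkaloid amides that dominate
# real dietary inhibitor hits) can be planted into a molecule; whether it
# was planted is the ground-truth structure-activity rule.

syn_rings <- c(
  "c{r}ccccc{r}", "c{r}ccncc{r}", "c{r}cncnc{r}", "c{r}ccoc{r}",
  "c{r}ccsc{r}", "c{r}cc[nH]c{r}", "C{r}CCCCC{r}", "C{r}CCCC{r}",
  "C{r}CCNCC{r}", "C{r}CCOCC{r}", "C{r}CCOC{r}", "C{r}CCSC{r}"
)
syn_linkers <- c(
  "C", "CC", "CCC", "C(C)C", "C(=O)", "C(=O)N", "C(=O)O", "N", "N(C)",
  "O", "OC", "S", "C=C", "CC(=O)", "NC(=O)", "OCC", "CN"
)
syn_terminals <- c(
  "C", "CC", "O", "N", "Cl", "F", "Br", "C#N", "C(=O)O", "C(F)(F)F",
  "[N+](=O)[O-]", "OC", "C(=O)N", "S", "C(C)(C)C"
)
syn_active_fragment <- "C(=O)N{r}CCCCC{r}"
syn_salts <- c(".[Na+]", ".[K+]", ".Cl", ".O", ".OS(=O)(=O)O")
syn_inorganics <- c(
  "[Na+].[Cl-]", "O", "OP(=O)(O)O", "OS(=O)(=O)O", "[K+].[Br-]",
  "N", "[Ca+2].[Cl-].[Cl-]", "[Mg+2].[O-]S(=O)(=O)[O-]"
)

assemble_smiles <- function(parts) {
  digit <- 0L
  paste(vapply(parts, function(p) {
    if (grepl("{r}", p, fixed = TRUE)) {
      digit <<- digit + 1L
      gsub("{r}", as.character(digit), p, fixed = TRUE)
    } else p
  }, character(1)), collapse = "")
}

generate_one_smiles <- function(with_substructure, max_linkers = 2) {
  parts <- sample(syn_rings, 1)
  for (i in seq_len(sample(0:max_linkers, 1))) {
    parts <- c(parts, sample(syn_linkers, 1))
    if (runif(1) < 0.5) parts <- c(parts, sample(syn_rings, 1))
  }
  if (with_substructure) {
    parts <- append(parts, syn_active_fragment,
                    after = sample(seq_along(parts), 1))
  }
  c(parts, sample(syn_terminals, 1))
}

#' Synthetic-library configuration
#'
#' Controls the composition of a generated compound library. Defaults mirror
#' the curated bioassay data the pipeline targets: roughly one compound in
#' six carries the active substructure (matching the ~1760:8893
#' active:inactive imbalance of the curated training data), with small
#' fractions of salt forms, planted duplicates and inorganic entries to
#' exercise curation.
#'
#' @param substructure_fraction Probability that a molecule carries the
#'   planted active substructure.
#' @param salt_fraction Fraction of entries emitted as salts/hydrates
#'   (counterion appended).
#' @param duplicate_fraction Fraction of entries that duplicate an earlier
#'   structure (each duplicate pairs with a distinct earlier molecule).
#' @param inorganic_fraction Fraction of entries that are inorganic species.
#' @param max_linkers Maximum chain-growth steps per molecule.
#' @return A `cyp_library_config` list.
#' @export
library_config <- function(substructure_fraction = 0.17,
                           salt_fraction = 0.05,
                           duplicate_fraction = 0,
                           inorganic_fraction = 0,
                           max_linkers = 3) {
  stopifnot(
    substructure_fraction >= 0, substructure_fraction <= 1,
    salt_fraction >= 0, duplicate_fraction >= 0, inorganic_fraction >= 0,
    duplicate_fraction + inorganic_fraction < 1
  )
  structure(
    list(substructure_fraction = substructure_fraction,
         salt_fraction = salt_fraction,
         duplicate_fraction = duplicate_fraction,
         inorganic_fraction = inorganic_fraction,
         max_linkers = max_linkers),
    class = "cyp_library_config"
  )
}

#' Generate a synthetic compound library
#'
#' Assembles `n` valid SMILES from the built-in fragment grammar, fully
#' reproducibly from `(seed, config)`. The returned tibble is its own
#' manifest: ground-truth columns record whether the active substructure was
#' planted (`has_substructure`), whether the entry is inorganic, carries a
#' salt, or duplicates an earlier entry (`duplicate_of`).
#'
#' @param n Number of library entries (>= 1).
#' @param seed Integer seed.
#' @param config A [library_config()].
#' @return A tibble with columns `compound_id`, `smiles`,
#'   `has_substructure`, `is_inorganic`, `has_salt`, `duplicate_of`.
#' @export
generate_library <- function(n, seed = 1, config = library_config()) {
  stopifnot(n >= 1, inherits(config, "cyp_library_config"))
  set.seed(seed)
  n_dup <- round(config$duplicate_fraction * n)
  n_inorg <- round(config$inorganic_fraction * n)
  n_base <- n - n_dup - n_inorg
  if (n_base < 1) cyp_abort("duplicate + inorganic fractions leave no base molecules",
                            class = "cyp_generator_error")
  if (n_dup > n_base) cyp_abort("duplicate_fraction too high for library size",
                                class = "cyp_generator_error")

  sub <- runif(n_base) < config$substructure_fraction
  smiles <- vapply(sub, function(s) {
    assemble_smiles(generate_one_smiles(s, config$max_linkers))
  }, character(1))
  salted <- runif(n_base) < config$salt_fraction
  smiles[salted] <- paste0(smiles[salted],
                           sample(syn_salts, sum(salted), replace = TRUE))
  base <- tibble(
    smiles = smiles, has_substructure = sub,
    is_inorganic = FALSE, has_salt = salted, dup_src = NA_integer_
  )
  inorg <- tibble(
    smiles = sample(syn_inorganics, n_inorg, replace = TRUE),
    has_substructure = FALSE, is_inorganic = TRUE, has_salt = FALSE,
    dup_src = NA_integer_
  )
  dup_src <- if (n_dup) sample(n_base, n_dup) else integer(0)
  dups <- base[dup_src, ]
  dups$dup_src <- dup_src
  out <- dplyr::bind_rows(base, inorg, dups)
  # deterministic interleaving so duplicates are not clustered at the end
  ord <- sample(nrow(out))
  out <- out[ord, , drop = FALSE]
  out$compound_id <- sprintf("SYN%06d", seq_len(nrow(out)))
  out$duplicate_of <- out$compound_id[match(match(out$dup_src, ord), seq_len(nrow(out)))]
  out$dup_src <- NULL
  dplyr::select(out, "compound_id", "smiles", "has_substructure",
                "is_inorganic", "has_salt", "duplicate_of")
}

#' Ground-truth structure-activity rule for planted bioassays
#'
#' @param p_active_given_substructure Probability that a molecule carrying
#'   the planted substructure is truly active.
#' @param background_active_probability Probability that a molecule without
#'   it is active.
#' @param label_noise Probability that a record's curve class is flipped
#'   relative to its true activity.
#' @param inconclusive_fraction Fraction of records assigned an
#'   inconclusive curve class (excluded by curation).
#' @param seed Integer seed used by [plant_bioassay()].
#' @return A `cyp_sar_truth` list.
#' @export
sar_truth <- function(p_active_given_substructure = 0.92,
                      background_active_probability = 0.013,
                      label_noise = 0, inconclusive_fraction = 0, seed = 1) {
  stopifnot(
    p_active_given_substructure >= 0, p_active_given_substructure <= 1,
    background_active_probability >= 0, background_active_probability <= 1,
    label_noise >= 0, label_noise <= 1,
    inconclusive_fraction >= 0, inconclusive_fraction < 1
  )
  structure(
    list(p_active_given_substructure = p_active_given_substructure,
         background_active_probability = background_active_probability,
         label_noise = label_noise,
         inconclusive_fraction = inconclusive_fraction, seed = seed),
    class = "cyp_sar_truth"
  )
}

# PubChem-style curve-class codes that curation must treat as inconclusive
syn_inconclusive_classes <- c(-2.2, -2.1, -1.2, 1.1, 2.0, 3.0)

#' Plant bioassay outcomes onto a library
#'
#' Draws a true activity for every library compound from the planted
#' structure-activity rule, then emits dose-response bioassay records:
#' actives get the full high-efficacy curve class (-1.1), an efficacy
#' uniform in \[80, 100\] percent and a potency log-uniform in
#' \[0.032, 15.85\] uM; inactives get curve class 4.0 and a sub-threshold
#' efficacy. A configurable fraction of records receives an inconclusive
#' curve class instead. The ground-truth activity is kept in `true_active`
#' (metadata a real download would not have).
#'
#' @param library A tibble from [generate_library()].
#' @param truth A [sar_truth()].
#' @return A tibble of bioassay records: `compound_id`, `smiles`,
#'   `curve_class`, `efficacy`, `potency`, plus ground-truth columns
#'   `true_active` and `has_substructure`.
#' @export
plant_bioassay <- function(library, truth = sar_truth()) {
  stopifnot(inherits(truth, "cyp_sar_truth"))
  n <- nrow(library)
  set.seed(truth$seed)
  p <- ifelse(library$has_substructure,
              truth$p_active_given_substructure,
              truth$background_active_probability)
  active <- runif(n) < p
  active[library$is_inorganic] <- FALSE
  observed <- active
  if (truth$label_noise > 0) {
    flip <- runif(n) < truth$label_noise
    observed <- xor(observed, flip)
  }
  inconclusive <- runif(n) < truth$inconclusive_fraction
  curve_class <- ifelse(observed, -1.1, 4.0)
  curve_class[inconclusive] <- sample(syn_inconclusive_classes,
                                      sum(inconclusive), replace = TRUE)
  efficacy <- ifelse(observed, runif(n, 80, 100), runif(n, 0, 20))
  potency <- ifelse(observed & !inconclusive,
                    10^runif(n, log10(0.032), log10(15.85)), NA_real_)
  tibble(
    compound_id = library$compound_id,
    smiles = library$smiles,
    curve_class = curve_class,
    efficacy = efficacy,
    potency = potency,
    true_active = active,
    has_substructure = library$has_substructure
  )
}

#' Simulate a dose-response inhibition curve
#'
#' Evaluates the four-parameter logistic at the assay's concentration series
#' (default: the seven 3-fold dilutions 125, 42, 14, 4.6, 1.5, 0.5,
#' 0.17 uM) and adds Gaussian noise per replicate measurement.
#'
#' @param ic50 True IC50 (uM, > 0).
#' @param hill Hill slope.
#' @param top,bottom Upper/lower activity asymptotes (percent of control).
#' @param noise_sd Gaussian noise standard deviation in percentage points.
#' @param concentrations Concentration series (uM).
#' @param replicates Replicates per concentration.
#' @param seed Integer seed.
#' @return A tibble with `concentration`, `replicate`, `activity`.
#' @export
simulate_curve <- function(ic50, hill = 1, top = 100, bottom = 0,
                           noise_sd = 5,
                           concentrations = c(125, 42, 14, 4.6, 1.5, 0.5, 0.17),
                           replicates = 3, seed = 1) {
  stopifnot(ic50 > 0, all(concentrations > 0), replicates >= 1)
  set.seed(seed)
  grid <- tidyr::expand_grid(
    concentration = concentrations,
    replicate = seq_len(replicates)
  )
  mu <- four_pl(grid$concentration, top, bottom, ic50, hill)
  dplyr::mutate(grid, activity = mu + rnorm(nrow(grid), 0, noise_sd))
}
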