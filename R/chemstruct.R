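#' Fingerprint configuration
#'
#' Describes the hashed molecular fingerprint used throughout a run. The
#' default is a circular (extended-connectivity) fingerprint of radius 2
#' (`"ECFP4"`, diameter-4 naming) at OpenBabel's fixed 4096-bit width; the
#' path-based `"FP2"` (1024 bits) and the keyed `"MACCS"` set are common
#' alternatives. One configuration must be used for a whole run: models,
#' applicability domains and screening sets are only comparable when their
#' fingerprints agree.
#'
#' @param type Fingerprint type, one of `"ECFP0"`, `"ECFP2"`, `"ECFP4"`,
#'   `"ECFP6"`, `"ECFP8"`, `"ECFP10"`, `"FP2"`, `"FP3"`, `"FP4"`, `"MACCS"`.
#' @return An object of class `cyp_fp_config`.
#' @examples
#' fp_config()
#' fp_config("FP2")
#' @export
fp_config <- function(type = "ECFP4") {
  type <- match.arg(type, c("ECFP0", "ECFP2", "ECFP4", "ECFP6", "ECFP8",
                            "ECFP10", "FP2", "FP3", "FP4", "MACCS"))
  structure(list(type = type, n_bits = NA_integer_), class = "cyp_fp_config")
}

#' @export
print.cyp_fp_config <- function(x, ...) {
  cat("<fingerprint config> type:", x$type,
      if (!is.na(x$n_bits)) paste0("(", x$n_bits, " bits)"), "\n")
  invisible(x)
}

fp_config_equal <- function(a, b) {
  identical(a$type, b$type) &&
    (is.na(a$n_bits) || is.na(b$n_bits) || a$n_bits == b$n_bits)
}

#' Parse and canonicalize SMILES structures
#'
#' Runs every structure through OpenBabel and records its canonical SMILES
#' and the number of dot-disconnected fragments in the input. Canonical forms
#' are idempotent and input-order independent, so two inputs naming the same
#' structure receive identical `smiles_canonical`. Failures are reported in
#' the `parse_error` column (or raised, with `strict = TRUE`) -- never
#' silently dropped.
#'
#' @param data A data frame of compounds.
#' @param smiles,id Columns holding the SMILES string and the compound
#'   identifier (unquoted; defaults `smiles`, `compound_id`).
#' @param strict If `TRUE`, the first unparsable structure raises a classed
#'   `cyp_parse_error` carrying the offending id. Default `FALSE`: failures
#'   are kept as rows with `parse_error` filled in.
#' @return The input tibble plus `smiles_canonical`, `n_fragments_input`,
#'   `heavy_atoms` and `parse_error` columns.
#' @examples
#' \donttest{
#' parse_smiles(tibble::tibble(compound_id = "etoh", smiles = "CCO"))
#' }
#' @export
parse_smiles <- function(data, smiles = smiles, id = compound_id,
                         strict = FALSE) {
  smi <- dplyr::pull(data, {{ smiles }})
  ids <- as.character(dplyr::pull(data, {{ id }}))
  syntax_ok <- vapply(smi, smiles_syntax_ok, logical(1), USE.NAMES = FALSE)
  can <- rep(NA_character_, length(smi))
  if (any(syntax_ok)) can[syntax_ok] <- ob_canonical(smi[syntax_ok])
  err <- dplyr::case_when(
    !syntax_ok ~ "malformed SMILES",
    is.na(can) | !nzchar(can) ~ "rejected by OpenBabel",
    TRUE ~ NA_character_
  )
  if (strict && any(!is.na(err))) {
    first <- which(!is.na(err))[1]
    parse_error(ids[first], err[first])
  }
  out <- dplyr::mutate(
    as_tibble(data),
    smiles_canonical = can,
    n_fragments_input = ifelse(
      is.na(can), NA_integer_,
      vapply(can, function(x) length(split_fragments(x)), integer(1),
             USE.NAMES = FALSE)
    ),
    heavy_atoms = ifelse(
      is.na(can), NA_integer_,
      vapply(can, count_heavy_atoms, integer(1), USE.NAMES = FALSE)
    ),
    parse_error = err
  )
  out
}

#' Desalt structures, keeping the largest organic fragment
#'
#' Multi-fragment structures (salts, hydrates) are reduced to the fragment
#' with the most heavy atoms that contains at least one carbon; equal-sized
#' candidates are broken by the canonical SMILES that sorts first
#' (deterministic). Single-fragment input passes through unchanged. Structures
#' with no carbon-containing fragment are inorganic: they get a
#' `desalt_error`, or raise a `cyp_inorganic_error` when `strict = TRUE`.
#'
#' The number of organic (carbon-containing) fragments in the input is kept
#' in `n_organic_fragments`; curation uses it to tell salts (one organic
#' fragment plus counterions) from true mixtures.
#'
#' @inheritParams parse_smiles
#' @param data A tibble that has been through [parse_smiles()].
#' @return `data` with `smiles_canonical` replaced by the desalted canonical
#'   structure and new `n_organic_fragments` and `desalt_error` columns.
#' @export
desalt <- function(data, id = compound_id, strict = FALSE) {
  stopifnot("smiles_canonical" %in% names(data))
  ids <- as.character(dplyr::pull(data, {{ id }}))
  can <- data$smiles_canonical
  n_org <- integer(length(can))
  kept <- can
  err <- rep(NA_character_, length(can))
  for (i in seq_along(can)) {
    if (is.na(can[i])) { n_org[i] <- NA_integer_; next }
    frags <- split_fragments(can[i])
    org <- frags[vapply(frags, contains_carbon, logical(1))]
    n_org[i] <- length(org)
    if (!length(org)) {
      if (strict) inorganic_error(ids[i])
      kept[i] <- NA_character_
      err[i] <- "no organic fragment"
      next
    }
    if (length(frags) == 1L) next
    sizes <- vapply(org, count_heavy_atoms, integer(1))
    best <- org[sizes == max(sizes)]
    kept[i] <- sort(best, method = "radix")[1]
  }
  # re-canonicalize the fragments we cut out of a larger string
  changed <- !is.na(kept) & kept != can & !is.na(can)
  if (any(changed)) kept[changed] <- ob_canonical(kept[changed])
  dplyr::mutate(
    as_tibble(data),
    smiles_canonical = kept,
    n_organic_fragments = n_org,
    desalt_error = err
  )
}

#' Compute physicochemical descriptors
#'
#' Adds molecular weight (g/mol, standard average atomic masses), calculated
#' octanol--water partition coefficient (OpenBabel's atom-contribution logP),
#' and hydrogen-bond donor/acceptor counts. Donors are OH/NH groups;
#' acceptors follow OpenBabel's `HBA2` definition (N and O atoms excluding
#' e.g. pyrrole-type nitrogens and amide resonance cases). One convention is
#' used for a whole run. Descriptors are only meaningful for desalted,
#' single-fragment structures.
#'
#' @param data A tibble with a `smiles_canonical` column (after
#'   [parse_smiles()], normally also [desalt()]).
#' @return `data` plus `mw`, `logp`, `hbd`, `hba` and `formula` columns.
#' @export
compute_descriptors <- function(data) {
  stopifnot("smiles_canonical" %in% names(data))
  ok <- !is.na(data$smiles_canonical)
  d <- ob_descriptors(data$smiles_canonical[ok])
  out <- as_tibble(data)
  out$mw <- out$logp <- NA_real_
  out$hbd <- out$hba <- NA_integer_
  out$formula <- NA_character_
  out$mw[ok] <- d$mw
  out$logp[ok] <- d$logp
  out$hbd[ok] <- d$hbd
  out$hba[ok] <- d$hba
  out$formula[ok] <- d$formula
  out
}

#' Fingerprint compounds
#'
#' Computes the configured hashed fingerprint for every structure. A
#' fingerprint is stored as a sorted integer vector of set-bit positions
#' (0-based); identical canonical structures always yield identical bit sets.
#'
#' @param data A tibble with a `smiles_canonical` column.
#' @param fp A [fp_config()].
#' @return `data` plus a `fingerprint` list-column; the realised
#'   configuration (with `n_bits` filled in) is attached as attribute
#'   `"fp_config"`.
#' @export
fingerprint_compounds <- function(data, fp = fp_config()) {
  stopifnot(inherits(fp, "cyp_fp_config"), "smiles_canonical" %in% names(data))
  ok <- !is.na(data$smiles_canonical)
  res <- ob_fingerprints(data$smiles_canonical[ok], type = fp$type)
  bits <- vector("list", nrow(data))
  bits[ok] <- res$bits
  fp$n_bits <- res$n_bits
  out <- dplyr::mutate(as_tibble(data), fingerprint = bits)
  attr(out, "fp_config") <- fp
  out
}

#' Tanimoto distance between two fingerprints
#'
#' `1 - |a intersect b| / |a union b|` over set-bit positions. Symmetric,
#' bounded in `[0, 1]`, and zero exactly for identical bit sets. Two empty
#' fingerprints are defined to be at distance 0.
#'
#' @param a,b Integer vectors of set-bit positions.
#' @return A single numeric distance in `[0, 1]`.
#' @examples
#' tanimoto_distance(c(1, 2, 3), c(2, 3, 4)) # 1 - 2/4 = 0.5
#' @export
tanimoto_distance <- function(a, b) {
  a <- unique(as.integer(a)); b <- unique(as.integer(b))
  if (!length(a) && !length(b)) return(0)
  i <- length(intersect(a, b))
  1 - i / (length(a) + length(b) - i)
}

# All pairwise Tanimoto distances between two fingerprint lists, via sparse
# bit-matrix cross products. Rows index `fps_a`, columns `fps_b`.
tanimoto_cross <- function(fps_a, fps_b, n_bits) {
  stopifnot(length(fps_a) > 0, length(fps_b) > 0)
  as_mat <- function(fps) {
    Matrix::sparseMatrix(
      i = rep(seq_along(fps), lengths(fps)),
      j = unlist(fps) + 1L, x = 1,
      dims = c(length(fps), n_bits)
    )
  }
  A <- as_mat(fps_a); B <- as_mat(fps_b)
  inter <- as.matrix(Matrix::tcrossprod(A, B))
  sizes_a <- lengths(lapply(fps_a, unique))
  sizes_b <- lengths(lapply(fps_b, unique))
  union <- outer(sizes_a, sizes_b, "+") - inter
  d <- 1 - inter / union
  d[union == 0] <- 0 # both fingerprints empty
  d
}

fp_matrix <- function(fps, n_bits) {
  Matrix::sparseMatrix(
    i = rep(seq_along(fps), lengths(fps)),
    j = unlist(fps) + 1L, x = 1,
    dims = c(length(fps), n_bits)
  )
}
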