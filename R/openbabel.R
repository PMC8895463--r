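# Thin wrapper around the OpenBabel command line (`obabel`). All structure
# chemistry -- canonical SMILES, molecular descriptors, hashed fingerprints --
# is delegated to it; this file only moves strings in and out.
#
# Conventions:
#   * molecules are keyed by internal row tokens ("r1", "r2", ...) so titles
#     never contain whitespace; results are matched back by token, and tokens
#     missing from the output mark parse failures.
#   * obabel runs with -e (continue after errors) so one bad row never takes
#     the batch down.

ob_available <- function() nzchar(Sys.which("obabel"))

ob_run <- function(smiles, extra_args) {
  stopifnot(is.character(smiles))
  if (!ob_available()) {
    cyp_abort("the 'obabel' executable is required but was not found on PATH",
              class = "cyp_backend_error")
  }
  tokens <- paste0("r", seq_along(smiles))
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".txt")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(smiles, tokens), fin)
  suppressWarnings(system2(
    "obabel", c(fin, extra_args, "-O", fout, "-e"),
    stdout = FALSE, stderr = FALSE
  ))
  lines <- if (file.exists(fout)) readLines(fout, warn = FALSE) else character(0)
  list(tokens = tokens, lines = lines)
}

# Canonical SMILES for each input; NA where OpenBabel rejects the structure.
ob_canonical <- function(smiles) {
  if (!length(smiles)) return(character(0))
  out <- ob_run(smiles, c("-ocan"))
  parts <- strsplit(out$lines, "\t", fixed = TRUE)
  got <- vapply(parts, function(p) trimws(p[2] %||% NA_character_), "")
  val <- vapply(parts, `[`, "", 1)
  setNames(val, got)[out$tokens]
}

# MW (average atomic masses), atom-contribution logP, H-bond donor and
# acceptor counts, and the molecular formula. NA rows where parsing fails.
ob_descriptors <- function(smiles) {
  n <- length(smiles)
  res <- tibble(
    mw = rep(NA_real_, n), logp = NA_real_,
    hbd = NA_integer_, hba = NA_integer_, formula = NA_character_
  )
  if (!n) return(res)
  out <- ob_run(smiles, c("-otxt", "--append", "MW logP HBD HBA2 formula"))
  parts <- strsplit(out$lines, "[ \t]+")
  ok <- lengths(parts) == 6
  parts <- parts[ok]
  idx <- match(vapply(parts, `[`, "", 1), out$tokens)
  res$mw[idx] <- as.numeric(vapply(parts, `[`, "", 2))
  res$logp[idx] <- as.numeric(vapply(parts, `[`, "", 3))
  res$hbd[idx] <- as.integer(vapply(parts, `[`, "", 4))
  res$hba[idx] <- as.integer(vapply(parts, `[`, "", 5))
  res$formula[idx] <- vapply(parts, `[`, "", 6)
  res
}

# Hashed fingerprints in FPS format -> list of sorted 0-based bit positions.
# NULL entries mark molecules OpenBabel could not process.
ob_fingerprints <- function(smiles, type = "ECFP4") {
  if (!length(smiles)) return(list(bits = list(), n_bits = NA_integer_))
  out <- ob_run(smiles, c("-ofps", paste0("-xf", type)))
  hdr <- out$lines[startsWith(out$lines, "#")]
  n_bits <- as.integer(sub("#num_bits=", "", hdr[startsWith(hdr, "#num_bits=")])[1])
  body <- out$lines[!startsWith(out$lines, "#") & nzchar(out$lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nm <- vapply(parts, function(p) p[2] %||% NA_character_, "")
  hex <- vapply(parts, `[`, "", 1)
  # the hex payload is the real bit space (the header rounds oddly for some
  # fingerprint families, e.g. FP2 reports 1021 bits in 256 hex digits)
  if (length(hex)) n_bits <- max(n_bits, 4L * nchar(hex[1]), na.rm = TRUE)
  lut <- lapply(0:15, function(v) which(bitwAnd(v, c(1L, 2L, 4L, 8L)) > 0L) - 1L)
  decode <- function(h) {
    ch <- strtoi(strsplit(h, "", fixed = TRUE)[[1]], 16L)
    nz <- which(ch > 0L)
    if (!length(nz)) return(integer(0))
    sort(unlist(lapply(nz, function(j) (j - 1L) * 4L + lut[[ch[j] + 1L]])))
  }
  bits <- lapply(hex, decode)
  names(bits) <- nm
  bits <- bits[out$tokens]
  names(bits) <- NULL
  list(bits = bits, n_bits = n_bits)
}

## ---- light-weight SMILES string utilities -------------------------------
## These do not parse chemistry (OpenBabel does); they tokenise the string
## for bookkeeping: well-formedness, fragment splitting, heavy-atom and
## carbon counts used by the desalting rules.

smiles_syntax_ok <- function(x) {
  if (is.na(x) || !nzchar(x)) return(FALSE)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  if (sum(chars == "(") != sum(chars == ")")) return(FALSE)
  if (sum(chars == "[") != sum(chars == "]")) return(FALSE)
  # ring-closure labels outside brackets must appear an even number of times
  bare <- gsub("\\[[^]]*\\]", "", x)
  labels <- c(
    regmatches(bare, gregexpr("%[0-9]{2}", bare))[[1]],
    strsplit(gsub("%[0-9]{2}", "", bare), "", fixed = TRUE)[[1]] |>
      (\(ch) ch[ch %in% as.character(0:9)])()
  )
  if (length(labels) && any(table(labels) %% 2 != 0)) return(FALSE)
  TRUE
}

split_fragments <- function(x) strsplit(x, ".", fixed = TRUE)[[1]]

# one token per atom: bracket atoms, Cl/Br, then the organic subset
smiles_atom_tokens <- function(x) {
  m <- gregexpr("\\[[^]]*\\]|Cl|Br|[BCNOPSFIbcnops]", x)
  regmatches(x, m)[[1]]
}

count_heavy_atoms <- function(x) {
  tok <- smiles_atom_tokens(x)
  sum(!grepl("^\\[[0-9]*H", tok)) # everything but bracketed hydrogen
}

bracket_element <- function(tok) {
  sub("^\\[[0-9]*([A-Za-z][a-z]?).*$", "\\1", tok)
}

contains_carbon <- function(x) {
  tok <- smiles_atom_tokens(x)
  if (!length(tok)) return(FALSE)
  brk <- startsWith(tok, "[")
  any(tok[!brk] %in% c("C", "c")) ||
    any(bracket_element(tok[brk]) %in% c("C", "c"))
}
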