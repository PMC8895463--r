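# Independent oracles and small fixtures, built in code.

# --- molecular-weight oracle: sum standard atomic masses over a formula ----
std_atomic_mass <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, P = 30.974, S = 32.06, Cl = 35.45,
  K = 39.098, Ca = 40.078, Br = 79.904, I = 126.904
)

mw_from_formula <- function(formula) {
  # strip charge suffixes like "C2H3O2-"
  formula <- gsub("[+-]+[0-9]*$", "", formula)
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  sum(vapply(toks, function(t) {
    el <- gsub("[0-9]", "", t)
    k <- suppressWarnings(as.integer(gsub("[A-Za-z]", "", t)))
    if (is.na(k)) k <- 1L
    unname(std_atomic_mass[el]) * k
  }, numeric(1)))
}

# --- brute-force set-based Tanimoto / APD oracle ---------------------------
tanimoto_oracle <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) && !length(b)) return(0)
  u <- length(union(a, b))
  1 - length(intersect(a, b)) / u
}

apd_oracle <- function(train_fps, z) {
  n <- length(train_fps)
  d <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) d <- c(d, tanimoto_oracle(train_fps[[i]], train_fps[[j]]))
  }
  m <- mean(d)
  sub <- d[d < m]
  if (!length(sub)) sub <- d
  s <- if (length(sub) > 1) stats::sd(sub) else 0
  mean(sub) + z * s
}

in_domain_oracle <- function(train_fps, query_fps, threshold) {
  vapply(query_fps, function(q) {
    nn <- min(vapply(train_fps, function(t) tanimoto_oracle(t, q), numeric(1)))
    nn <= threshold
  }, logical(1))
}

# --- per-item counting oracle for confusion metrics ------------------------
metrics_oracle <- function(tp, fp, tn, fn) {
  truth <- c(rep(TRUE, tp + fn), rep(FALSE, fp + tn))
  pred <- c(rep(TRUE, tp), rep(FALSE, fn), rep(TRUE, fp), rep(FALSE, tn))
  n <- length(truth)
  se <- if (tp + fn > 0) sum(truth & pred) / sum(truth) else NA_real_
  sp <- if (tn + fp > 0) sum(!truth & !pred) / sum(!truth) else NA_real_
  ef <- if (tp + fp > 0 && tp + fn > 0 && n > 0) {
    (sum(truth & pred) / sum(pred)) / (sum(truth) / n)
  } else NA_real_
  num <- sum(truth & pred) * sum(!truth & !pred) -
    sum(!truth & pred) * sum(truth & !pred)
  den <- sqrt(prod(c(sum(pred), sum(truth), sum(!pred), sum(!truth))))
  mcc <- if (den > 0) num / den else 0
  list(se = se, sp = sp, ef = ef, mcc = mcc)
}

# --- tiny hand-listed molecule set for descriptor checks -------------------
# (name, SMILES) pairs with unambiguous structures
oracle_molecules <- tibble::tribble(
  ~compound_id, ~smiles,
  "methane", "C",
  "ethanol", "CCO",
  "acetic_acid", "CC(=O)O",
  "benzene", "c1ccccc1",
  "toluene", "Cc1ccccc1",
  "phenol", "Oc1ccccc1",
  "aniline", "Nc1ccccc1",
  "pyridine", "c1ccncc1",
  "cyclohexane", "C1CCCCC1",
  "acetone", "CC(C)=O",
  "acetamide", "CC(N)=O",
  "chlorobenzene", "Clc1ccccc1",
  "furan", "c1ccoc1",
  "thiophene", "c1ccsc1",
  "glycine", "NCC(=O)O",
  "dimethyl_ether", "COC",
  "acetonitrile", "CC#N",
  "nitrobenzene", "O=[N+]([O-])c1ccccc1",
  "benzoic_acid", "OC(=O)c1ccccc1",
  "naphthalene", "c1ccc2ccccc2c1"
)

# attach/propagate the fingerprint configuration through dplyr verbs that
# drop attributes
with_fp_config <- function(data, template) {
  attr(data, "fp_config") <- attr(template, "fp_config")
  data
}
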