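# Published marker-id row labels (discovery/validation overlap table) used
# as the parser round-trip fixture; en dash as printed.
table2_labels <- c(
  "A2MG (1424) – 5402",
  "A2MG (247) – 5200",
  "A2MG (247) – 5401",
  "A2MG (55) – 5411",
  "A2MG (55) – 5412",
  "A2MG (869) – 5200",
  "A2MG (869) – 6200",
  "A2MG (869) – 6300",
  "A2MG (991) – 5402",
  "AFAM (33) – 5402",
  "HPT (207 and 211) – 5401 and 5402",
  "IGG1 (297) – 5411",
  "A2MG – AIGYLNTGYQR",
  "A2MG – TEHPFTVEEFVLPK"
)

# literal step-up rule, executed naively: q_(i) = min_{j: p_(j) >= p_(i)}
# m * p_(j) / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(seq(i, m), function(j) m * ps[j] / j, numeric(1))
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# AUROC by enumerating every positive-negative pair; ties count 1/2
auc_oracle <- function(scores, labels) {
  y <- factor(labels)
  sp <- scores[y == levels(y)[2L]]
  sn <- scores[y == levels(y)[1L]]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(sp) * length(sn))
}

# brute-force motif-group matcher over spec rows
motif_oracle <- function(codes, specs) {
  comp <- parse_glycan_code(codes)
  lapply(seq_len(nrow(specs)), function(i) {
    hits <- logical(length(codes))
    for (k in seq_along(codes)) {
      ok <- TRUE
      for (f in c("fucose", "sialic", "hexose", "hexnac")) {
        v <- specs[[f]][i]
        if (!is.na(v) && comp[[f]][k] != v) ok <- FALSE
      }
      hits[k] <- ok
    }
    which(hits)
  })
}

# small cohort config for fast tests
small_config <- function(seed, ...) {
  args <- list(seed = seed, n_control = 12L, n_nash = 8L, n_hcc = 8L,
               n_proteins = 6L, n_glycoproteins = 5L, n_glycopeptides = 30L,
               qc_interval = 5L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}
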