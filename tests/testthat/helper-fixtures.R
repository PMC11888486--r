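# Shared fixtures and independent oracles, all built in code.

# Small, fast cohort configuration: tiny event counts via the clamp.
tiny_config <- function(groups = c("NIND", "MS"), master_seed = 10L,
                        n_donors = 3L, clamp = c(200L, 400L)) {
  cfg <- build_default_config(groups, master_seed = master_seed,
                              event_clamp = clamp)
  for (g in names(cfg$groups)) cfg$groups[[g]]$n_donors <- n_donors
  cfg
}

# Blank event tibble (all channels at the negative state).
blank_events <- function(n) {
  m <- matrix(0, nrow = n, ncol = 17,
              dimnames = list(NULL, csf_marker_panel()))
  tibble::as_tibble(as.data.frame(m, check.names = FALSE))
}

# The eight-event worked example: one archetype event per major population
# plus one CD45-negative event.
toy_events <- function() {
  ev <- blank_events(8)
  set <- function(i, ...) {
    vals <- list(...)
    for (ch in names(vals)) ev[i, ch] <<- vals[[ch]]
  }
  set(1, CD45 = 4, CD14 = 4)
  set(2, CD45 = 4, CD3 = 4, CD4 = 4, CD27 = 4, CD45RA = 0)
  set(3, CD45 = 4, CD3 = 4, CD8 = 4, CD27 = 4, CD45RA = 4)
  set(4, CD45 = 4, CD19 = 4, CD27 = 6, CD38 = 6)
  set(5, CD45 = 4, CD56 = 4)
  set(6, CD45 = 4, `HLA-DR` = 4, CD11c = 4)
  set(7, CD45 = 4, SSC = 6)
  set(8, CD45 = 0)
  ev
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# choose(nx+ny, nx) group assignments of the pooled sample (tie-free input).
wilcox_p_enum <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(n, nx)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * (n - nx) / 2
  min(1, mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12))
}

# Brute-force Mann-Whitney pair fraction (ties one half).
auc_pairs_brute <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Write a minimal FCS 3.1 file (list mode, float32, little-endian).
write_fcs_fixture <- function(path, data, short_names = colnames(data),
                              stain_names = colnames(data)) {
  npar <- ncol(data); ntot <- nrow(data)
  d <- "/"
  kv <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", npar, "$TOT", ntot, "$NEXTDATA", "0")
  for (i in seq_len(npar))
    kv <- c(kv, paste0("$P", i, "N"), short_names[i],
            paste0("$P", i, "S"), stain_names[i],
            paste0("$P", i, "B"), "32",
            paste0("$P", i, "E"), "0,0",
            paste0("$P", i, "R"), "262144")
  text <- paste0(d, paste(kv, collapse = d), d)
  text_start <- 58
  text_end <- text_start + nchar(text) - 1
  data_start <- text_end + 1
  data_end <- data_start + 4 * npar * ntot - 1
  pad8 <- function(x) formatC(x, width = 8)
  header <- paste0("FCS3.1", "    ", pad8(text_start), pad8(text_end),
                   pad8(data_start), pad8(data_end), pad8(0), pad8(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(as.matrix(data))), con, size = 4,
           endian = "little")
  invisible(path)
}
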