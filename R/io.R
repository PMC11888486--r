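# Canonical CSV interchange, YAML config/tree serialization, and a reader
# for FCS 3.0/3.1 files.

#' Write / read per-donor event CSV
#'
#' One CSV per donor: header = the 17 panel channel names plus an optional
#' `latent_label` column (synthetic data only); UTF-8, "." decimal.
#'
#' @param events Event tibble.
#' @param path File path.
#' @return `read_events_csv` returns the event tibble; writers return the
#'   path invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events, check.names = FALSE), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(csf_marker_panel(), names(df))
  if (length(missing))
    stop_cytocsf(path, " is missing channel column(s): ",
                 paste(missing, collapse = ", "))
  tibble::as_tibble(df)
}

#' Write / read the cohort metadata CSV
#'
#' Columns: donor_id, group, age, sex, concentration_cells_per_uL, treated,
#' volume_mL.
#'
#' @param metadata Metadata tibble.
#' @param path File path.
#' @export
write_metadata_csv <- function(metadata, path) {
  utils::write.csv(as.data.frame(metadata), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_metadata_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("donor_id", "group", "age", "sex", "concentration_cells_per_uL",
            "treated", "volume_mL")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_cytocsf(path, " is missing column(s): ",
                 paste(missing, collapse = ", "))
  tibble::as_tibble(df)
}

#' Write / read population counts as long-format CSV
#'
#' Long format `donor_id, population, count`; reading returns a named list
#' of `csf_population_counts` (one per donor), with `n_events` restored from
#' the root leukocyte count plus the non-leukocyte remainder column
#' `n_events` written alongside.
#'
#' @param counts_by_donor Named list of `csf_population_counts`.
#' @param path File path.
#' @export
write_counts_csv <- function(counts_by_donor, path) {
  rows <- lapply(names(counts_by_donor), function(id) {
    cnt <- counts_by_donor[[id]]
    data.frame(donor_id = id, population = cnt$population,
               count = cnt$count,
               n_events = attr(cnt, "n_events"))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_csv
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path)
  out <- lapply(split(df, factor(df$donor_id, unique(df$donor_id))),
                function(d) {
    cnt <- tibble::tibble(population = d$population, count = d$count)
    attr(cnt, "n_events") <- d$n_events[1]
    attr(cnt, "donor_id") <- d$donor_id[1]
    class(cnt) <- c("csf_population_counts", class(cnt))
    cnt
  })
  out[unique(df$donor_id)]
}

#' Serialize a gate tree to / from YAML
#'
#' Nodes are written in definition order with their name, parent, marker
#' predicates and any union/complement membership.
#'
#' @param tree A `csf_gate_tree`.
#' @param path YAML file path.
#' @export
write_gate_tree_yaml <- function(tree, path) {
  nodes <- lapply(tree, function(n) {
    out <- list(name = n$name,
                parent = if (is.na(n$parent)) NULL else n$parent)
    if (length(n$predicates))
      out$predicates <- lapply(n$predicates, function(p)
        list(channel = p$channel, state = p$state))
    if (!is.null(n$union_of)) out$union_of <- as.list(n$union_of)
    if (!is.null(n$complement_of)) out$complement_of <- n$complement_of
    out
  })
  yaml::write_yaml(nodes, path)
  invisible(path)
}

#' @rdname write_gate_tree_yaml
#' @export
read_gate_tree_yaml <- function(path) {
  nodes <- yaml::read_yaml(path)
  tree <- lapply(nodes, function(n) {
    gate_node(n$name, n$parent %||% NA_character_,
              predicates = lapply(n$predicates %||% list(), function(p)
                pred(p$channel, p$state)),
              union_of = if (!is.null(n$union_of)) unlist(n$union_of),
              complement_of = n$complement_of)
  })
  tree <- structure(tree, class = "csf_gate_tree")
  validate_gate_tree(tree)
  tree
}

#' Serialize a cohort configuration to / from YAML
#'
#' @param config A `csf_cohort_config`.
#' @param path YAML file path.
#' @export
write_config_yaml <- function(config, path) {
  ser <- unclass(config)
  ser$expression <- as.list(unclass(ser$expression))
  ser$groups <- lapply(ser$groups, function(g)
    lapply(g, function(x) if (is.null(names(x))) x else as.list(x)))
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  named_vec <- c("composition", "subset_t", "cm_em_temra_cd4",
                 "cm_em_temra_cd8", "th_states", "naive_cd8")
  groups <- lapply(raw$groups, function(g) {
    for (f in intersect(named_vec, names(g))) g[[f]] <- unlist(g[[f]])
    g$age_range <- as.numeric(unlist(g$age_range))
    g$n_donors <- as.integer(g$n_donors)
    g
  })
  cfg <- structure(
    list(panel = unlist(raw$panel),
         expression = structure(raw$expression,
                                class = "csf_expression_model"),
         groups = groups,
         volume_ml = raw$volume_ml,
         event_clamp = as.integer(unlist(raw$event_clamp)),
         dirichlet_conc = raw$dirichlet_conc,
         master_seed = as.integer(raw$master_seed)),
    class = "csf_cohort_config")
  for (g in cfg$groups) validate_group_spec(g)
  validate_config(cfg)
}

#' Read an FCS 3.0/3.1 file
#'
#' Minimal reader for list-mode FCS 3.0/3.1: parses the header offsets and
#' TEXT segment, reads float (`$DATATYPE F`), double (`D`) or integer (`I`)
#' list-mode DATA, names columns by `$PnS` (stain) falling back to `$PnN`
#' (short name), and applies the arcsinh transform
#' `asinh(x / cofactor)` to every channel mapped onto a fluorescence channel
#' of the panel (side scatter is left untransformed).
#'
#' @param path FCS file path.
#' @param cofactor Arcsinh cofactor for fluorescence channels (default 150).
#' @param channel_map Optional named character vector mapping panel names to
#'   file channel names (`c("CD45" = "FJComp-BUV805-A", ...)`); by default
#'   panel names are matched to file channel names directly.
#' @param transform Apply the arcsinh transform? (`TRUE` by default.)
#' @return Event tibble with the matched panel channels first.
#' @export
read_fcs <- function(path, cofactor = 150, channel_map = NULL,
                     transform = TRUE) {
  raw <- readBin(path, "raw", file.size(path))
  hdr <- rawToChar(raw[1:58])
  version <- trimws(substr(hdr, 1, 6))
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop_cytocsf(path, ": unsupported FCS version '", version, "'")
  off <- function(a, b) suppressWarnings(as.numeric(trimws(substr(hdr, a, b))))
  tb <- off(11, 18); te <- off(19, 26); db <- off(27, 34); de <- off(35, 42)
  txt <- rawToChar(raw[(tb + 1):(te + 1)])
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  keys <- toupper(trimws(parts[seq(1, length(parts) - 1, by = 2)]))
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- stats::setNames(vals, keys)
  getkw <- function(k) if (k %in% names(kw)) kw[[k]] else NULL
  if (!identical(toupper(trimws(getkw("$MODE") %||% "")), "L"))
    stop_cytocsf(path, ": only list-mode ($MODE L) FCS is supported")
  npar <- as.integer(getkw("$PAR")); ntot <- as.integer(getkw("$TOT"))
  if (db == 0) db <- as.numeric(getkw("$BEGINDATA"))
  if (de == 0) de <- as.numeric(getkw("$ENDDATA"))
  dtype <- toupper(trimws(getkw("$DATATYPE") %||% ""))
  endian <- if (identical(trimws(getkw("$BYTEORD") %||% ""), "4,3,2,1"))
    "big" else "little"
  bits <- as.integer(getkw("$P1B"))
  data_raw <- raw[(db + 1):(de + 1)]
  values <- switch(dtype,
    F = readBin(data_raw, "numeric", n = npar * ntot, size = 4,
                endian = endian),
    D = readBin(data_raw, "numeric", n = npar * ntot, size = 8,
                endian = endian),
    I = readBin(data_raw, "integer", n = npar * ntot, size = bits / 8,
                endian = endian, signed = bits > 16),
    stop_cytocsf(path, ": unsupported $DATATYPE '", dtype, "'"))
  mat <- matrix(values, nrow = ntot, ncol = npar, byrow = TRUE)
  ch_names <- vapply(seq_len(npar), function(i) {
    s <- getkw(paste0("$P", i, "S"))
    n <- getkw(paste0("$P", i, "N"))
    if (!is.null(s) && nzchar(trimws(s))) trimws(s) else trimws(n)
  }, "")
  colnames(mat) <- ch_names
  panel <- csf_marker_panel()
  map <- channel_map %||% stats::setNames(panel, panel)
  found <- intersect(names(map), panel)
  found <- found[map[found] %in% ch_names]
  out <- mat[, map[found], drop = FALSE]
  colnames(out) <- found
  if (transform) {
    fluor <- setdiff(found, "SSC")
    out[, fluor] <- asinh(out[, fluor] / cofactor)
  }
  rest <- mat[, setdiff(ch_names, map[found]), drop = FALSE]
  tibble::as_tibble(as.data.frame(cbind(out, rest), check.names = FALSE))
}
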