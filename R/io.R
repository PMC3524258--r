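#' Export a network as CSV tables
#'
#' Writes `species.csv` (canonical label, type, membrane flag, partition
#' class, moiety counts) and `reactions.csv` (reactants, products, rate-law
#' class, rate constant) for the chemistry-level network.
#'
#' @param network a `raft_network`.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
export_network_csv <- function(network, dir = ".") {
  stopifnot(inherits(network, "raft_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- file.path(dir, "species.csv")
  rx <- file.path(dir, "reactions.csv")
  utils::write.csv(network$chem$species, sp, row.names = FALSE, quote = FALSE)
  utils::write.csv(network$chem$reactions, rx, row.names = FALSE,
                   quote = FALSE)
  invisible(c(species = sp, reactions = rx))
}

#' Export the chemistry network in a BNGL-style subset
#'
#' Writes molecule types, seed species and the flat unidirectional
#' reaction list in a BioNetGen-compatible subset so the generated network
#' can be cross-checked with external rule-based modeling tools. The file
#' is re-readable with [read_bngl_subset()].
#'
#' @param network a `raft_network`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
export_bngl_subset <- function(network, path) {
  stopifnot(inherits(network, "raft_network"))
  p <- network$params
  mols <- network$chem$model$molecules
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# FcERI raft model network (BNGL subset export)")
  w("begin molecule types")
  for (m in mols) {
    comps <- vapply(m$components, function(cm) {
      if (is.null(cm$states)) cm$site
      else paste0(cm$site, "~", paste(cm$states, collapse = "~"))
    }, "")
    w("  %s(%s)", m$name, paste(comps, collapse = ","))
  }
  w("end molecule types")
  w("begin seed species")
  seeds <- c("R(0;Y;Y)", "Lyn", "Syk(00)", "LAT(U)", "Grb2")
  tot <- c(p$rec_total, p$lyn_total, p$syk_total, p$lat_total, p$grb2_total)
  for (i in seq_along(seeds))
    if (seeds[i] %in% network$chem$species$label)
      w("  %s %g", seeds[i], tot[i])
  w("end seed species")
  w("begin reactions")
  r <- network$chem$reactions
  for (i in seq_len(nrow(r))) {
    lhs <- if (nzchar(r$r2[i])) paste(r$r1[i], "+", r$r2[i]) else r$r1[i]
    rhs <- if (nzchar(r$p2[i])) paste(r$p1[i], "+", r$p2[i]) else r$p1[i]
    w("  %s -> %s %g # %s", lhs, rhs, r$k[i], r$class[i])
  }
  w("end reactions")
  invisible(path)
}

#' Read a BNGL-subset network file
#'
#' Parses a file written by [export_bngl_subset()], returning the species
#' labels and the reaction table.
#'
#' @param path file path.
#' @return list with `species` (character) and `reactions` (data.frame).
#' @export
read_bngl_subset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  sec <- NULL
  rx <- list(); seeds <- character(0)
  for (ln in lines) {
    t <- trimws(sub("#.*$", "", ln))
    if (!nzchar(t)) next
    if (grepl("^begin ", t)) { sec <- sub("^begin ", "", t); next }
    if (grepl("^end ", t)) { sec <- NULL; next }
    if (identical(sec, "seed species"))
      seeds <- c(seeds, strsplit(t, "[[:space:]]+")[[1]][1])
    if (identical(sec, "reactions")) {
      parts <- strsplit(t, "->", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop("malformed reaction line: ", ln)
      lhs <- trimws(strsplit(parts[1], "+", fixed = TRUE)[[1]])
      rhs_tok <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
      k <- as.numeric(rhs_tok[length(rhs_tok)])
      rhs <- trimws(strsplit(paste(rhs_tok[-length(rhs_tok)],
                                   collapse = " "),
                             "+", fixed = TRUE)[[1]])
      rx[[length(rx) + 1L]] <- list(lhs = lhs, rhs = rhs, k = k)
    }
  }
  species <- sort(unique(c(seeds,
                           unlist(lapply(rx, function(r) c(r$lhs, r$rhs))))))
  reactions <- data.frame(
    r1 = vapply(rx, function(r) r$lhs[1], ""),
    r2 = vapply(rx, function(r) if (length(r$lhs) > 1) r$lhs[2] else "", ""),
    p1 = vapply(rx, function(r) r$rhs[1], ""),
    p2 = vapply(rx, function(r) if (length(r$rhs) > 1) r$rhs[2] else "", ""),
    k = vapply(rx, function(r) r$k, 0))
  list(species = species, reactions = reactions)
}

#' Write a tidy CSV of an experiment result
#'
#' Long format `time, observable, value, alpha, lambda` for
#' dephosphorylation time courses, or the long dose-response table.
#'
#' @param x a `raft_dephos` or `raft_dose_response`.
#' @param path output CSV.
#' @return invisibly, `path`.
#' @export
write_timecourse_csv <- function(x, path) {
  if (inherits(x, "raft_dephos")) {
    df <- as.data.frame(x)
    df$lambda <- attr(x, "lambda")
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (inherits(x, "raft_dose_response")) {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                     quote = FALSE)
  } else stop("unsupported object")
  invisible(path)
}
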