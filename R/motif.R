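#' Motif scan configuration
#'
#' Patterns (POSIX regular expressions over the amino-acid alphabet) for
#' the conserved LAT signaling panel: the juxtamembrane palmitoylation
#' cysteine pair `C-x(1,4)-C` searched within an N-terminal window, the
#' PLC-gamma binding tyrosine motif (default the exact tetrapeptide
#' `YLVV`), Grb2-type `Y-x-N` docking motifs, the exact LCK-binding
#' hexapeptide `PIPRSP`, the reference-numbered proline-rich region, and
#' the reference-numbered docking tyrosine positions.
#'
#' @param dicys_pattern dicysteine pattern (default `"C.{1,4}C"`)
#' @param dicys_window 1-based inclusive search window (default `c(1, 45)`)
#' @param plc_pattern PLC-gamma motif pattern (default exact `"YLVV"`)
#' @param grb2_pattern Grb2-type motif pattern (default `"Y.N"`)
#' @param lck_pattern LCK-binding motif (default exact `"PIPRSP"`)
#' @param proline_region reference-numbered 1-based inclusive interval
#'   (default `c(30, 100)`)
#' @param docking_positions reference-numbered docking tyrosines
#'   (default `c(132, 171, 191, 226)`)
#' @return a `motif_config` list
#' @export
motif_config <- function(dicys_pattern = "C.{1,4}C",
                         dicys_window = c(1L, 45L),
                         plc_pattern = "YLVV",
                         grb2_pattern = "Y.N",
                         lck_pattern = "PIPRSP",
                         proline_region = c(30L, 100L),
                         docking_positions = c(132L, 171L, 191L, 226L)) {
  stopifnot(nzchar(dicys_pattern), nzchar(plc_pattern),
            nzchar(grb2_pattern), nzchar(lck_pattern),
            length(dicys_window) == 2L, dicys_window[1L] >= 1L,
            dicys_window[1L] <= dicys_window[2L],
            length(proline_region) == 2L,
            proline_region[1L] <= proline_region[2L])
  cfg <- list(dicys_pattern = dicys_pattern,
              dicys_window = as.integer(dicys_window),
              plc_pattern = plc_pattern,
              grb2_pattern = grb2_pattern,
              lck_pattern = lck_pattern,
              proline_region = as.integer(proline_region),
              docking_positions = as.integer(docking_positions))
  class(cfg) <- "motif_config"
  cfg
}

#' Scan a protein for the conserved LAT signaling motif panel
#'
#' All reported positions are 1-based on the ungapped query protein. The
#' PLC-gamma context class is derived from the residue immediately
#' N-terminal to the matched PLC-gamma motif tyrosine: `glycine` when G
#' (the tetrapod arrangement that makes the tyrosine a suboptimal ZAP-70
#' substrate), `acidic` when D or E (the fish arrangement), `other`
#' otherwise, `absent` when the motif is not found. The proline fraction
#' is `#P / region length` over the reference-mapped proline region when
#' an alignment and reference row are supplied, otherwise over the raw
#' interval clipped to the protein.
#'
#' @param protein protein string or one-record protein [seq_set()]
#' @param config a [motif_config()]
#' @param aln optional [msa()] containing the query for reference mapping
#' @param query_id,ref_id row ids of the query and the reference in `aln`
#' @return a `motif_report` list: `dicysteine` (`found`, `position`),
#'   `plc` (`found`, `tyrosine_position`, `context_class`,
#'   `context_residue`), `grb2` (Y positions of `Y-x-N` matches), `lck`
#'   (`found`, `position`), `proline_fraction`, and, when `aln` is given,
#'   `docking_conserved` (named logical per reference position)
#' @export
motif_scan <- function(protein, config = motif_config(), aln = NULL,
                       query_id = NULL, ref_id = NULL) {
  if (inherits(protein, "seq_set") || is.data.frame(protein))
    protein <- protein$residues[1L]
  stopifnot(nchar(protein) >= 1L)
  L <- nchar(protein)

  win <- pmin(config$dicys_window, L)
  wseq <- substr(protein, win[1L], win[2L])
  m <- regexpr(config$dicys_pattern, wseq)
  dicys <- list(found = m > 0L,
                position = if (m > 0L) win[1L] + as.integer(m) - 1L
                           else NA_integer_)

  m <- regexpr(config$plc_pattern, protein)
  if (m > 0L) {
    match_str <- substr(protein, m, m + attr(m, "match.length") - 1L)
    y_off <- regexpr("Y", match_str, fixed = TRUE)
    ypos <- as.integer(m) + as.integer(y_off) - 1L
    ctx <- if (ypos > 1L) substr(protein, ypos - 1L, ypos - 1L) else ""
    cls <- if (ctx == "G") "glycine" else if (ctx %in% c("D", "E")) "acidic"
           else "other"
    plc <- list(found = TRUE, tyrosine_position = ypos,
                context_class = cls, context_residue = ctx)
  } else {
    plc <- list(found = FALSE, tyrosine_position = NA_integer_,
                context_class = "absent", context_residue = NA_character_)
  }

  g <- gregexpr(config$grb2_pattern, protein)[[1L]]
  grb2 <- if (g[1L] > 0L) as.integer(g) else integer(0)

  m <- regexpr(config$lck_pattern, protein)
  lck <- list(found = m > 0L,
              position = if (m > 0L) as.integer(m) else NA_integer_)

  reg <- config$proline_region
  if (!is.null(aln)) {
    if (is.null(query_id) || is.null(ref_id))
      stop("query_id and ref_id are required with an alignment")
    qpos <- vapply(reg[1L]:reg[2L], function(p) {
      mp <- map_ref_position(aln, ref_id, p)
      mp$position[mp$id == query_id]
    }, integer(1))
    qpos <- qpos[!is.na(qpos)]
    np <- sum(substring(protein, qpos, qpos) == "P")
  } else {
    lo <- min(reg[1L], L); hi <- min(reg[2L], L)
    np <- nchar(gsub("[^P]", "", substr(protein, lo, hi)))
  }
  proline_fraction <- np / (reg[2L] - reg[1L] + 1L)

  out <- list(dicysteine = dicys, plc = plc, grb2 = grb2, lck = lck,
              proline_fraction = proline_fraction)
  if (!is.null(aln)) {
    cons <- vapply(config$docking_positions, function(p) {
      mp <- map_ref_position(aln, ref_id, p)
      identical(mp$residue[mp$id == query_id], "Y")
    }, logical(1))
    out$docking_conserved <- setNames(cons,
                                      paste0("Y", config$docking_positions))
  }
  class(out) <- "motif_report"
  out
}

#' @export
print.motif_report <- function(x, ...) {
  cat("<motif_report>\n")
  cat(sprintf("  dicysteine: %s%s\n",
              if (x$dicysteine$found) "found" else "absent",
              if (x$dicysteine$found)
                sprintf(" at %d", x$dicysteine$position) else ""))
  cat(sprintf("  PLC-gamma motif: %s (context %s)\n",
              if (x$plc$found)
                sprintf("Y at %d", x$plc$tyrosine_position) else "absent",
              x$plc$context_class))
  cat(sprintf("  Grb2-type Y-x-N: %d site(s)%s\n", length(x$grb2),
              if (length(x$grb2))
                paste0(" at ", paste(x$grb2, collapse = ", ")) else ""))
  cat(sprintf("  LCK-binding PIPRSP: %s\n",
              if (x$lck$found) sprintf("found at %d", x$lck$position)
              else "absent"))
  cat(sprintf("  proline fraction in region: %.3f\n", x$proline_fraction))
  if (!is.null(x$docking_conserved))
    cat(sprintf("  docking tyrosines conserved: %s\n",
                paste(names(x$docking_conserved)[x$docking_conserved],
                      collapse = ", ")))
  invisible(x)
}

#' Tabulate motif reports for a set of proteins
#'
#' Runs [motif_scan()] on every sequence and returns one row per protein,
#' suitable for writing as the motif TSV of the `verify` workflow.
#'
#' @param proteins protein [seq_set()]
#' @param config a [motif_config()]
#' @param aln optional [msa()] of the same sequences for
#'   reference-numbered mapping
#' @param ref_id reference row id in `aln`
#' @return data frame with one row per protein
#' @export
motif_table <- function(proteins, config = motif_config(), aln = NULL,
                        ref_id = NULL) {
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    r <- motif_scan(proteins$residues[i], config, aln = aln,
                    query_id = proteins$id[i], ref_id = ref_id)
    base <- data.frame(
      id = proteins$id[i],
      dicysteine_found = r$dicysteine$found,
      dicysteine_position = r$dicysteine$position,
      plc_found = r$plc$found,
      plc_tyrosine_position = r$plc$tyrosine_position,
      plc_context_class = r$plc$context_class,
      n_grb2_sites = length(r$grb2),
      lck_piprsp_found = r$lck$found,
      proline_fraction = r$proline_fraction,
      stringsAsFactors = FALSE)
    if (!is.null(r$docking_conserved))
      base <- cbind(base, as.data.frame(as.list(r$docking_conserved)))
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
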