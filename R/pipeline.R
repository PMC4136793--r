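#' Default pipeline configuration
#'
#' One list holding every stage's tunables with their documented
#' defaults: the small-ORF size filter (10--100 aa), the maturation
#' grammar windows, the hydropathy TM caller settings (Kyte-Doolittle,
#' window 19, threshold 1.6, min length 15, merge gap 3), the
#' receptor-like tail threshold (50 aa), alignment scoring (BLOSUM62,
#' gap open 10, extend 0.5), and qPCR settings (efficiency 2,
#' monokaryon calibrator).
#'
#' @param ... Named overrides of individual defaults.
#' @return A list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    min_aa = 10L, max_aa = 100L,
    cleavage_window = c(13L, 19L),
    accept_len = c(9L, 15L), preferred_len = c(12L, 13L),
    mode = "strict",
    hydropathy_window = 19L, tm_threshold = 1.6,
    tm_min_len = 15L, tm_merge_gap = 3L,
    tail_threshold = 50L,
    substitution_matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5,
    identity_mode = "full",
    efficiency = 2, calibrator = "monokaryon",
    min_overlap = 100L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full locus-annotation pipeline
#'
#' Orchestrates merge -> six-frame ORF scan -> pheromone classification
#' -> receptor annotation and pairwise identity -> locus map (with
#' optional in-silico PCR) -> optional calibrated expression, and
#' collects a machine-readable summary.
#'
#' @param contig_a First contig ([contig()], string, or a FASTA path
#'   holding one or two contigs).
#' @param contig_b Second contig, or `NULL` when `contig_a` already is
#'   the full assembly (or a two-record FASTA).
#' @param receptors Receptor cDNA/protein input ([analyze_receptors()]
#'   forms), or `NULL` to skip receptor annotation.
#' @param ct Ct table (`data.frame` or CSV path), or `NULL`.
#' @param primers Length-2 character vector `c(fwd, rev)`, or `NULL`.
#' @param config A [default_config()] list.
#' @param out_dir When given, reports (summary JSON, ORF/pheromone/
#'   receptor/expression CSVs, map GFF3) are written there.
#' @return An object of class `b3_pipeline`; its `summary` element
#'   holds the headline numbers (gene counts, mating span, identity
#'   matrix, expression folds).
#' @export
run_pipeline <- function(contig_a, contig_b = NULL, receptors = NULL,
                         ct = NULL, primers = NULL,
                         config = default_config(), out_dir = NULL) {
  if (is.character(contig_a) && length(contig_a) == 1L && file.exists(contig_a)) {
    ctgs <- read_contigs(contig_a)
    contig_a <- ctgs[[1L]]
    if (is.null(contig_b) && length(ctgs) >= 2L) contig_b <- ctgs[[2L]]
  }
  assembly <- .stage("merge", {
    if (is.null(contig_b)) {
      seq <- .contig_seq(contig_a)
      if (nchar(seq) == 0L) stop("empty input sequence")
      structure(list(sequence = seq,
                     contig_offsets = c(1L), overlap_len = 0L,
                     b_orientation = NA_character_),
                class = "locus_assembly")
    } else merge_contigs(contig_a, contig_b, min_overlap = config$min_overlap)
  })

  orfs <- .stage("orf_scan",
    six_frame_orfs(assembly$sequence, config$min_aa, config$max_aa,
                   id = "assembly"))

  precursors <- .stage("pheromone_classification",
    scan_pheromones(orfs, min_aa = config$min_aa, max_aa = config$max_aa,
                    window = config$cleavage_window,
                    accept_len = config$accept_len,
                    preferred_len = config$preferred_len,
                    mode = config$mode))
  ph_report <- precursor_report(precursors)
  if (nrow(ph_report) > 0L)
    ph_report <- cbind(name = paste0("pheromone_", seq_len(nrow(ph_report))),
                       ph_report, stringsAsFactors = FALSE)

  receptor_ann <- NULL; idmat <- NULL; rec_feats <- NULL
  if (!is.null(receptors)) {
    receptor_ann <- .stage("receptor_annotation",
      analyze_receptors(receptors, tail_threshold = config$tail_threshold,
                        window = config$hydropathy_window,
                        threshold = config$tm_threshold,
                        min_len = config$tm_min_len,
                        merge_gap = config$tm_merge_gap))
    idmat <- .stage("receptor_identity",
      identity_matrix(receptors, mode = config$identity_mode,
                      substitution_matrix = config$substitution_matrix,
                      gap_open = config$gap_open,
                      gap_extend = config$gap_extend))
    # genomic placement requires nucleotide input
    rec_in <- .as_nucleotide_set(receptors)
    if (!is.null(rec_in)) {
      rec_feats <- .stage("receptor_placement", {
        rows <- lapply(names(rec_in), function(nm) {
          hit <- locate_cds(rec_in[[nm]], assembly)
          if (is.null(hit)) return(NULL)
          gene_features(nm, "receptor", hit$start, hit$end, hit$strand)
        })
        rows <- rows[!vapply(rows, is.null, logical(1L))]
        if (length(rows)) do.call(rbind, rows) else NULL
      })
    }
  }

  map <- .stage("locus_map", {
    feats <- if (nrow(ph_report) > 0L)
      gene_features(ph_report$name, "pheromone", ph_report$start,
                    ph_report$end, ph_report$strand) else
      gene_features(character(), character(), integer(), integer(),
                    character(), character())
    if (!is.null(rec_feats)) feats <- rbind(feats, rec_feats)
    scar <- NULL
    if (!is.null(primers)) {
      amp <- locate_amplicon(primers[1L], primers[2L], assembly)
      if (!is.null(amp)) scar <- c(min(amp$start), max(amp$end))
    }
    locus_map(feats, assembly, scar_interval = scar)
  })

  expr <- NULL
  if (!is.null(ct)) {
    expr <- .stage("expression", {
      records <- if (is.character(ct)) read_ct_table(ct) else ct
      rel <- relative_expression(records, calibrator = config$calibrator,
                                 efficiency = config$efficiency)
      expression_stats(rel)
    })
  }

  summary <- list(
    assembly_length = nchar(assembly$sequence),
    overlap_len = assembly$overlap_len,
    n_orfs = nrow(orfs),
    n_pheromones = length(precursors),
    n_receptors = if (is.null(receptor_ann)) NA_integer_ else
      sum(receptor_ann$report$seven_tm),
    n_receptor_like = if (is.null(receptor_ann)) NA_integer_ else
      sum(receptor_ann$report$receptor_like),
    mating_span_nt = map$mating_span_nt,
    scar_interval = map$scar_interval,
    mature_lengths = ph_report$mature_length,
    identity_pct = idmat,
    folds = if (is.null(expr)) NULL else expr$table)

  res <- structure(list(assembly = assembly, orfs = orfs,
                        precursors = precursors, pheromone_report = ph_report,
                        receptors = receptor_ann, identity = idmat,
                        map = map, expression = expr,
                        config = config, summary = summary),
                   class = "b3_pipeline")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

## nucleotide view of the receptor input, or NULL for protein input
.as_nucleotide_set <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    set <- Biostrings::readBStringSet(x)
    seqs <- as.character(set)
    names(seqs) <- sub("\\s.*$", "", names(set))
    if (all(grepl("^[ACGTNacgtn]+$", seqs))) return(toupper(seqs))
    return(NULL)
  }
  if (inherits(x, "DNAStringSet")) {
    seqs <- as.character(x)
    if (is.null(names(seqs))) names(seqs) <- paste0("cds_", seq_along(seqs))
    return(seqs)
  }
  if (is.character(x) && all(grepl("^[ACGTNacgtn]+$", x))) {
    if (is.null(names(x))) names(x) <- paste0("cds_", seq_along(x))
    return(toupper(x))
  }
  NULL
}

#' Write pipeline reports
#'
#' @param x A `b3_pipeline` object.
#' @param dir Output directory.
#' @export
write_pipeline <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- x$summary
  s$identity_pct <- if (is.null(s$identity_pct)) NULL else
    as.data.frame(s$identity_pct)
  s$scar_interval <- if (is.null(s$scar_interval)) NULL else
    as.integer(s$scar_interval)
  jsonlite::write_json(s, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  write_orf_table(x$orfs, file.path(dir, "orfs.csv"))
  utils::write.csv(x$pheromone_report, file.path(dir, "pheromones.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(x$receptors))
    write_receptor_report(x$receptors, file.path(dir, "receptors.csv"))
  if (!is.null(x$expression))
    write_expression(x$expression$table, file.path(dir, "expression.csv"))
  write_annotation(x$map$features, file.path(dir, "map.gff3"),
                   format = "gff3", assembly_length = x$map$assembly_length)
  invisible(dir)
}

#' @export
print.b3_pipeline <- function(x, ...) {
  s <- x$summary
  cat("<b3 locus pipeline>\n")
  cat("  assembly:", s$assembly_length, "nt (overlap", s$overlap_len, "nt)\n")
  cat("  small ORFs scanned:", s$n_orfs, "\n")
  cat("  pheromone precursors:", s$n_pheromones, "\n")
  if (!is.na(s$n_receptors))
    cat("  7-TM receptors:", s$n_receptors,
        "( receptor-like:", s$n_receptor_like, ")\n")
  if (!is.na(s$mating_span_nt))
    cat("  mating-gene span:", s$mating_span_nt, "nt\n")
  if (!is.null(s$scar_interval))
    cat("  marker amplicon:", s$scar_interval[1], "-", s$scar_interval[2], "\n")
  invisible(x)
}
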