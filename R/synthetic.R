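.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
.TM_AA <- c("I", "L", "V", "F", "A", "M")
.LOOP_AA <- c("R", "K", "D", "E", "S", "T", "N", "Q", "G", "P")

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

.random_aa <- function(n, exclude = character()) {
  pool <- setdiff(.AA20, exclude)
  sample(pool, n, replace = TRUE)
}

## Random codon encoding of a peptide; `*` appends a stop codon.
.encode_peptide <- function(peptide, add_stop = TRUE) {
  tab <- .codon_table()
  v <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  if (add_stop) v <- c(v, "*")
  paste(vapply(v, function(aa) {
    cods <- tab[[aa]]
    if (length(cods) == 1L) cods else sample(cods, 1L)
  }, ""), collapse = "")
}

## Grammar-complete precursor peptide of length L with mature length m.
## Avoids internal Met (no nested ORFs) and any non-truth Arg whose
## offset would admit a competing cleavage site.
.build_precursor_peptide <- function(L, m, window = c(13L, 19L)) {
  o <- m + 4L
  if (L < m + 9L) stop("infeasible precursor length ", L, " for mature length ", m)
  rp <- L - o + 1L
  v <- character(L)
  banned_r <- seq_len(L)[(L - seq_len(L) + 1L) >= window[1] &
                           (L - seq_len(L) + 1L) <= window[2]]
  for (i in seq_len(L)) {
    v[i] <- if (i %in% banned_r) sample(setdiff(.AA20, c("M", "R")), 1L)
            else sample(setdiff(.AA20, "M"), 1L)
  }
  v[1L] <- "M"
  v[rp - 4L] <- "P"
  v[rp - 2L] <- sample(c("D", "N"), 1L)
  v[rp - 1L] <- sample(c("E", "T"), 1L)
  v[rp] <- "R"
  v[L - 3L] <- "C"
  paste(v, collapse = "")
}

#' Generate a synthetic pheromone precursor gene
#'
#' Emits an intron-free small ORF carrying the full maturation grammar:
#' ATG start, ER/TR doublet with Pro at -4 and Asp/Asn at -2 relative to
#' the cut site, positioned so the mature peptide (doublet-adjacent
#' through the CaaX cysteine) has the requested length, a Cys at the 4th
#' position from the C-terminus, and a stop codon. Codons are drawn at
#' random from the standard code; the peptide contains no internal Met,
#' and no Arg is placed where it could seed a competing cleavage site.
#'
#' @param precursor_len_range Codon-count range for the precursor
#'   peptide (default 57--61).
#' @param mature_len_range Mature peptide length range (default 12--13).
#' @param window Cleavage-site offset window the truth site must respect.
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @return A list: `dna` (CDS with stop), `peptide`, `mature_peptide`,
#'   `doublet`, `doublet_end_offset`, `caax_motif`, `length_aa`.
#' @export
generate_precursor_gene <- function(precursor_len_range = c(57L, 61L),
                                    mature_len_range = c(12L, 13L),
                                    window = c(13L, 19L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(precursor_len_range[1] <= precursor_len_range[2],
            mature_len_range[1] <= mature_len_range[2])
  if (mature_len_range[2] + 4L > window[2] || mature_len_range[1] + 4L < window[1])
    stop("mature length range incompatible with cleavage-site window")
  if (precursor_len_range[1] < mature_len_range[2] + 9L)
    stop("precursor too short to carry the maturation grammar")
  Ls <- seq.int(precursor_len_range[1], precursor_len_range[2])
  ms <- seq.int(mature_len_range[1], mature_len_range[2])
  L <- Ls[sample.int(length(Ls), 1L)]
  m <- ms[sample.int(length(ms), 1L)]
  pep <- .build_precursor_peptide(L, m, window)
  n <- nchar(pep)
  o <- m + 4L
  list(dna = .encode_peptide(pep),
       peptide = pep,
       mature_peptide = substr(pep, n - o + 2L, n - 3L),
       doublet = substr(pep, n - o, n - o + 1L),
       doublet_end_offset = o,
       caax_motif = substr(pep, n - 3L, n),
       length_aa = L)
}

#' Generate a synthetic pheromone-receptor gene
#'
#' Emits an intron-free CDS whose translation has exactly `n_tm`
#' hydrophobic stretches of `tm_len` residues (drawn from
#' I/L/V/F/A/M) separated by hydrophilic loops (R/K/D/E/S/T/N/Q/G/P),
#' with an N-terminal extracellular segment of `n_tail` residues and a
#' C-terminal cytoplasmic tail of `tail_len` residues. The default
#' geometry (57-aa N-tail, 21-aa TMs, 15-aa loops) gives protein lengths
#' of 294 + tail_len, so tails of 34/126/264/176 reproduce the deposited
#' receptor lengths 328/420/558/470 aa.
#'
#' @param tail_len C-terminal cytoplasmic tail length in residues.
#' @param n_tail N-terminal segment length (default 57).
#' @param tm_len TM segment length (default 21).
#' @param loop_len Inter-TM loop length (default 15).
#' @param n_tm Number of TM segments (default 7).
#' @param seed Optional seed.
#' @return A list: `dna` (CDS with stop), `peptide`, `tm_segments`
#'   (`data.frame` of truth start/end), `n_tail_len`, `c_tail_len`.
#' @export
generate_receptor_gene <- function(tail_len, n_tail = 57L, tm_len = 21L,
                                   loop_len = 15L, n_tm = 7L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(tail_len >= 0L, n_tail >= 1L, tm_len >= 1L, loop_len >= 1L)
  parts <- list(c("M", sample(.LOOP_AA, n_tail - 1L, replace = TRUE)))
  starts <- integer(n_tm)
  pos <- n_tail
  for (k in seq_len(n_tm)) {
    starts[k] <- pos + 1L
    parts[[length(parts) + 1L]] <- sample(.TM_AA, tm_len, replace = TRUE)
    pos <- pos + tm_len
    if (k < n_tm) {
      parts[[length(parts) + 1L]] <- sample(.LOOP_AA, loop_len, replace = TRUE)
      pos <- pos + loop_len
    }
  }
  if (tail_len > 0L)
    parts[[length(parts) + 1L]] <- sample(.LOOP_AA, tail_len, replace = TRUE)
  pep <- paste(unlist(parts), collapse = "")
  list(dna = .encode_peptide(pep),
       peptide = pep,
       tm_segments = data.frame(start = starts, end = starts + tm_len - 1L),
       n_tail_len = n_tail,
       c_tail_len = tail_len)
}

.default_layout <- function() {
  data.frame(
    name = c("PEphb3.1", "PEphb3.2", "PESTE3.3.1", "PEphb3.3",
             "PESTE3.3.2", "PESTE3.3.3", "PEphb3.4", "PESTE3.3.4"),
    kind = c("pheromone", "pheromone", "receptor", "pheromone",
             "receptor", "receptor", "pheromone", "receptor"),
    start = c(26325L, 27056L, 28186L, 29629L, 30416L, 32405L, 35693L, 36579L),
    strand = c("+", "-", "+", "+", "-", "+", "-", "+"),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic mating-type locus
#'
#' Collects the generator's study conditions: a ~60-kb region carried on
#' two clones of 40.4 kb and 32.7 kb sharing a 13.1-kb exact overlap,
#' four pheromone precursor genes (57--61 codons, mature peptides 12--13
#' aa) and four seven-TM receptor genes laid out at the published
#' coordinates, grammar-ablated decoy ORFs in the flanks, a 2.1-kb
#' marker amplicon in the overlap region, and per-gene
#' monokaryon-over-dikaryon expression folds inside the reported ranges
#' (receptors 3.8--12.2, pheromones 1.5--31.4).
#'
#' @param seed Seed fixing all randomness.
#' @param len_a,len_b,overlap Clone lengths and exact overlap (nt).
#' @param background_gc Background GC fraction (i.i.d. composition).
#' @param layout Gene layout `data.frame` (`name`, `kind`, `start`,
#'   `strand`).
#' @param precursor_len_range,mature_len_range Pheromone geometry.
#' @param receptor_tail_lens Named per-receptor C-tail lengths (aa).
#' @param decoy_count Number of decoy ORFs (grammar ablations).
#' @param amplicon_start,amplicon_len,primer_len Marker amplicon
#'   geometry.
#' @param fold_map Named per-gene injected expression fold
#'   (first-condition over second-condition).
#' @param noise_sd,replicates,efficiency,ref_ct,base_ct Ct-table
#'   simulation settings.
#' @return A list of class `locus_spec`.
#' @export
locus_spec <- function(seed = 42L, len_a = 40400L, len_b = 32700L,
                       overlap = 13100L, background_gc = 0.5,
                       layout = .default_layout(),
                       precursor_len_range = c(57L, 61L),
                       mature_len_range = c(12L, 13L),
                       receptor_tail_lens = c(PESTE3.3.1 = 34L, PESTE3.3.2 = 126L,
                                              PESTE3.3.3 = 264L, PESTE3.3.4 = 176L),
                       decoy_count = 6L,
                       amplicon_start = 33000L, amplicon_len = 2100L,
                       primer_len = 20L,
                       fold_map = c(PEphb3.1 = 1.5, PEphb3.2 = 31.4,
                                    PEphb3.3 = 5, PEphb3.4 = 10,
                                    PESTE3.3.1 = 3.8, PESTE3.3.2 = 5,
                                    PESTE3.3.3 = 9, PESTE3.3.4 = 12.2),
                       noise_sd = 0.1, replicates = 3L, efficiency = 2,
                       ref_ct = 15, base_ct = 22) {
  stopifnot(overlap < min(len_a, len_b), background_gc > 0, background_gc < 1)
  structure(list(seed = as.integer(seed), len_a = len_a, len_b = len_b,
                 overlap = overlap, background_gc = background_gc,
                 layout = layout,
                 precursor_len_range = precursor_len_range,
                 mature_len_range = mature_len_range,
                 receptor_tail_lens = receptor_tail_lens,
                 decoy_count = decoy_count,
                 amplicon_start = amplicon_start, amplicon_len = amplicon_len,
                 primer_len = primer_len,
                 fold_map = fold_map, noise_sd = noise_sd,
                 replicates = replicates, efficiency = efficiency,
                 ref_ct = ref_ct, base_ct = base_ct),
            class = "locus_spec")
}

## ---- decoys: grammar ablations -------------------------------------------

.build_decoy_peptide <- function(type, window = c(13L, 19L)) {
  L <- if (type == "oversize") 110L else sample(20:80, 1L)
  if (type == "oversize") return(.build_precursor_peptide(L, 12L, window))
  banned_r <- seq_len(L)[(L - seq_len(L) + 1L) >= window[1] &
                           (L - seq_len(L) + 1L) <= window[2]]
  v <- character(L)
  for (i in seq_len(L)) {
    v[i] <- if (type == "no_doublet" && i %in% banned_r)
      sample(setdiff(.AA20, c("M", "R")), 1L) else sample(setdiff(.AA20, "M"), 1L)
  }
  v[1L] <- "M"
  if (type == "no_caax") {
    # intact doublet + context, but no CaaX cysteine
    rp <- L - 15L
    v[rp - 4L] <- "P"; v[rp - 2L] <- "D"; v[rp - 1L] <- "E"; v[rp] <- "R"
    v[L - 3L] <- sample(setdiff(.AA20, c("C", "M")), 1L)
  } else {
    v[L - 3L] <- "C"                      # no_doublet keeps the CaaX
  }
  paste(v, collapse = "")
}

## ---- assembly sanitation --------------------------------------------------

## Middle base (forward coordinates) of peptide codon `idx` of an ORF.
.codon_mid <- function(orf_start, orf_end, strand, idx) {
  if (strand == "+") orf_start + 3L * (idx - 1L) + 1L
  else orf_end - (3L * (idx - 1L) + 1L)
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## Synonymously recode the host-gene codon covering forward position
## `pos` so that the base at `pos` changes. Returns updated chars or NULL.
.syn_recode <- function(chars, pos, host) {
  gc <- Biostrings::GENETIC_CODE
  stops <- names(gc)[gc == "*"]
  if (host$strand == "+") {
    ci <- (pos - host$start) %/% 3L
    fs <- host$start + 3L * ci
    codon <- paste(chars[fs:(fs + 2L)], collapse = "")
    k <- pos - fs + 1L
  } else {
    ci <- (host$end - pos) %/% 3L
    fs <- host$end - 3L * ci - 2L
    codon <- paste(.COMP[rev(chars[fs:(fs + 2L)])], collapse = "")
    k <- (host$end - 3L * ci) - pos + 1L
  }
  aa <- if (codon %in% stops) "*" else unname(gc[codon])
  syn <- if (identical(aa, "*")) stops else names(gc)[gc == aa]
  syn <- syn[substr(syn, k, k) != substr(codon, k, k)]
  if (length(syn) == 0L) return(NULL)
  new <- sort(syn)[1L]
  nv <- strsplit(new, "")[[1L]]
  if (host$strand == "+") chars[fs:(fs + 2L)] <- nv
  else chars[fs:(fs + 2L)] <- unname(.COMP[rev(nv)])
  chars
}

## Remove every strict-grammar pheromone call outside the truth set by
## deterministic single-base edits (or synonymous recoding inside
## protected truth genes). Guarantees generator precision 1.0.
.sanitize_assembly <- function(chars, truth_orfs, protected_ranges,
                               min_aa = 10L, max_aa = 100L,
                               window = c(13L, 19L), max_iter = 40L) {
  N <- length(chars)
  prot <- logical(N)
  for (i in seq_len(nrow(protected_ranges)))
    prot[protected_ranges$start[i]:protected_ranges$end[i]] <- TRUE
  hosts <- protected_ranges[protected_ranges$coding, , drop = FALSE]
  truth_key <- paste(truth_orfs$start, truth_orfs$end, truth_orfs$strand)
  for (iter in seq_len(max_iter)) {
    assembly <- paste(chars, collapse = "")
    orfs <- six_frame_orfs(assembly, min_aa, max_aa, id = "assembly")
    extras <- NULL
    for (i in seq_len(nrow(orfs))) {
      key <- paste(orfs$start[i], orfs$end[i], orfs$strand[i])
      if (key %in% truth_key) next
      p <- classify_pheromone(orfs[i, , drop = FALSE], min_aa = min_aa,
                              max_aa = max_aa, window = window, mode = "strict")
      if (!is.null(p)) { extras <- orfs[i, , drop = FALSE]; break }
    }
    if (is.null(extras)) return(chars)
    len <- extras$length_aa
    sites <- enumerate_cleavage_sites(extras$peptide, window)
    idx <- c(1L, len - 3L, len - sites$doublet_end_offset + 1L)
    fixed <- FALSE
    for (pi in idx) {
      pos <- .codon_mid(extras$start, extras$end, extras$strand, pi)
      if (!prot[pos]) {
        # replace with C (forward G on the minus strand): kills an ATG
        # start, a TGY cysteine or an R codon without creating any of them
        chars[pos] <- if (extras$strand == "+") "C" else "G"
        fixed <- TRUE
        break
      }
      host_i <- which(hosts$start <= pos & hosts$end >= pos)
      if (length(host_i) == 1L) {
        upd <- .syn_recode(chars, pos, hosts[host_i, , drop = FALSE])
        if (!is.null(upd)) { chars <- upd; fixed <- TRUE; break }
      }
    }
    if (!fixed)
      stop("sanitize: could not break chance pheromone ORF at ",
           extras$start, "-", extras$end, extras$strand)
  }
  stop("sanitize: did not converge in ", max_iter, " passes")
}

## ---- full locus ------------------------------------------------------------

#' Generate a truth-labelled synthetic mating-type locus
#'
#' Builds the full simulated input set for the pipeline: an i.i.d.
#' background sequence with intron-free pheromone and receptor genes
#' embedded at the layout coordinates, decoy ORFs in the flanks, a
#' marker amplicon with its primer pair, the split into two overlapping
#' clone contigs, and a replicate Ct table with the injected expression
#' folds. After embedding, the background is sanitized so that no ORF
#' outside the truth set passes the strict pheromone grammar; the
#' emitted truth is therefore exhaustive. All randomness derives from
#' `spec$seed` (single stream).
#'
#' @param spec A [locus_spec()].
#' @return A list of class `synthetic_locus`: `contigs` (two
#'   [contig()]s), `assembly` (the full sequence), `truth` (features,
#'   mature peptides, TM segments, receptor proteins/cDNA, primers,
#'   amplicon, fold map), `ct` (the Ct table) and `spec`.
#' @export
generate_locus <- function(spec = locus_spec()) {
  stopifnot(inherits(spec, "locus_spec"))
  set.seed(spec$seed)
  N <- spec$len_a + spec$len_b - spec$overlap
  gcp <- spec$background_gc
  chars <- sample(c("A", "C", "G", "T"), N, replace = TRUE,
                  prob = c((1 - gcp) / 2, gcp / 2, gcp / 2, (1 - gcp) / 2))

  layout <- spec$layout
  feats <- list(); mature <- list(); tmsegs <- list()
  rec_prot <- list(); rec_cdna <- list()
  truth_orfs <- list()
  for (i in seq_len(nrow(layout))) {
    nm <- layout$name[i]; kind <- layout$kind[i]
    st <- layout$start[i]; strand <- layout$strand[i]
    if (kind == "pheromone") {
      g <- generate_precursor_gene(spec$precursor_len_range,
                                   spec$mature_len_range)
      mature[[nm]] <- g$mature_peptide
    } else {
      tail_len <- spec$receptor_tail_lens[[nm]]
      g <- generate_receptor_gene(tail_len)
      tmsegs[[nm]] <- g$tm_segments
      rec_prot[[nm]] <- g$peptide
      rec_cdna[[nm]] <- g$dna
    }
    dna <- g$dna
    en <- st + nchar(dna) - 1L
    if (en > N) stop("layout: gene ", nm, " exceeds assembly bounds")
    ins <- if (strand == "+") dna else reverse_complement(dna)
    chars[st:en] <- strsplit(ins, "")[[1L]]
    feats[[length(feats) + 1L]] <- gene_features(nm, kind, st, en, strand)
    if (kind == "pheromone")
      truth_orfs[[length(truth_orfs) + 1L]] <-
        data.frame(start = st, end = en, strand = strand,
                   stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, feats)
  if (any(features$start[-1L] <= features$end[-nrow(features)]))
    stop("layout: overlapping gene features")

  # decoys in the flanks, well clear of the gene block and amplicon
  decoy_left <- c(2000L, 5500L, 9000L, 12500L, 16000L, 19500L)
  decoy_right <- c(42000L, 45500L, 49000L, 52500L, 56000L, 58500L)
  pool <- as.vector(rbind(decoy_left, decoy_right))
  if (spec$decoy_count > length(pool)) stop("too many decoys for the flank pool")
  types <- rep(c("no_caax", "no_doublet", "oversize"),
               length.out = spec$decoy_count)
  decoy_feats <- list()
  for (i in seq_len(spec$decoy_count)) {
    pep <- .build_decoy_peptide(types[i])
    dna <- .encode_peptide(pep)
    st <- pool[i]; en <- st + nchar(dna) - 1L
    strand <- if (i %% 2L == 0L) "-" else "+"
    ins <- if (strand == "+") dna else reverse_complement(dna)
    chars[st:en] <- strsplit(ins, "")[[1L]]
    decoy_feats[[i]] <- gene_features(paste0("decoy_", i), "other",
                                      st, en, strand, note = types[i])
  }
  decoys <- if (length(decoy_feats)) do.call(rbind, decoy_feats) else
    gene_features(character(), character(), integer(), integer(),
                  character(), character())

  # marker amplicon: primer pair read off the assembly, checked unique
  amp_start <- spec$amplicon_start
  pl <- spec$primer_len
  assembly_str <- paste(chars, collapse = "")
  n_hits <- function(p) {
    subj <- Biostrings::DNAString(assembly_str)
    length(Biostrings::matchPattern(Biostrings::DNAString(p), subj)) +
      length(Biostrings::matchPattern(
        Biostrings::DNAString(reverse_complement(p)), subj))
  }
  for (try in 1:50) {
    amp_end <- amp_start + spec$amplicon_len - 1L
    fwd <- substr(assembly_str, amp_start, amp_start + pl - 1L)
    rev <- reverse_complement(substr(assembly_str, amp_end - pl + 1L, amp_end))
    if (n_hits(fwd) == 1L && n_hits(rev) == 1L) break
    amp_start <- amp_start + 97L
    if (try == 50L) stop("could not place a unique primer pair")
  }

  protected <- rbind(
    data.frame(start = features$start, end = features$end,
               strand = features$strand, coding = TRUE,
               stringsAsFactors = FALSE),
    data.frame(start = c(amp_start, amp_end - pl + 1L),
               end = c(amp_start + pl - 1L, amp_end),
               strand = "+", coding = FALSE, stringsAsFactors = FALSE))
  chars <- .sanitize_assembly(chars, do.call(rbind, truth_orfs), protected)
  assembly_str <- paste(chars, collapse = "")
  if (n_hits(fwd) != 1L || n_hits(rev) != 1L)
    stop("primer uniqueness lost during sanitation")

  ct <- generate_ct_table(spec$fold_map, noise_sd = spec$noise_sd,
                          replicates = spec$replicates,
                          efficiency = spec$efficiency,
                          ref_ct = spec$ref_ct, base_ct = spec$base_ct)

  contig_a <- contig("ctgA", substr(assembly_str, 1L, spec$len_a),
                     source = "synthetic")
  contig_b <- contig("ctgB", substr(assembly_str, spec$len_a - spec$overlap + 1L, N),
                     source = "synthetic")
  structure(list(
    contigs = list(contig_a, contig_b),
    assembly = assembly_str,
    truth = list(features = features, decoys = decoys,
                 mature_peptides = unlist(mature),
                 tm_segments = tmsegs,
                 receptor_proteins = unlist(rec_prot),
                 receptor_cdna = unlist(rec_cdna),
                 primers = c(fwd = fwd, rev = rev),
                 amplicon = c(start = amp_start, end = amp_end),
                 overlap_len = spec$overlap,
                 fold_map = spec$fold_map,
                 seed = spec$seed),
    ct = ct,
    spec = spec), class = "synthetic_locus")
}

#' @export
print.synthetic_locus <- function(x, ...) {
  cat("<synthetic locus>", nchar(x$assembly), "nt on 2 contigs (overlap",
      x$truth$overlap_len, "nt), seed", x$truth$seed, "\n")
  cat("  truth genes:", nrow(x$truth$features), "(",
      sum(x$truth$features$kind == "pheromone"), "pheromone /",
      sum(x$truth$features$kind == "receptor"), "receptor ) +",
      nrow(x$truth$decoys), "decoys\n")
  cat("  amplicon:", x$truth$amplicon["start"], "-", x$truth$amplicon["end"], "\n")
  invisible(x)
}

#' Simulate a replicate qRT-PCR Ct table
#'
#' The internal-standard (reference) Ct is a constant plus Gaussian
#' cycle noise; the target Ct is offset so that
#' `efficiency^(delta-delta-Ct)` equals the injected fold in
#' expectation. The injected fold is expression in the first condition
#' over the second, so the second condition's target Ct is raised by
#' `log(fold)/log(efficiency)` cycles.
#'
#' @param fold_map Named numeric vector of per-gene folds (> 0).
#' @param conditions Two condition labels; the first is the calibrator.
#' @param replicates Replicates per (gene, condition) (default 3).
#' @param noise_sd Gaussian Ct noise, cycles (default 0.1).
#' @param efficiency Amplification factor (default 2).
#' @param ref_ct,base_ct Reference and calibrator-condition target Ct.
#' @param seed Optional seed.
#' @return A Ct `data.frame` (`gene`, `condition`, `replicate`,
#'   `ct_target`, `ct_reference`).
#' @export
generate_ct_table <- function(fold_map,
                              conditions = c("monokaryon", "dikaryon"),
                              replicates = 3L, noise_sd = 0.1,
                              efficiency = 2, ref_ct = 15, base_ct = 22,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(fold_map > 0), replicates >= 1L, length(conditions) == 2L)
  out <- list()
  for (g in names(fold_map)) {
    shift <- c(0, log(fold_map[[g]]) / log(efficiency))
    for (ci in 1:2) for (r in seq_len(replicates)) {
      out[[length(out) + 1L]] <- data.frame(
        gene = g, condition = conditions[ci], replicate = r,
        ct_target = base_ct + shift[ci] + stats::rnorm(1L, 0, noise_sd),
        ct_reference = ref_ct + stats::rnorm(1L, 0, noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write a synthetic locus to disk
#'
#' Emits `contigs.fasta`, `truth.gff3` (genes and decoys),
#' `mature.faa`, `receptors.faa`, `receptors_cdna.fna`, `ct.csv`,
#' `primers.csv` and a `config.txt` echo of the generating spec
#' (including the seed). Identical spec + seed give byte-identical
#' files.
#'
#' @param sim A `synthetic_locus` from [generate_locus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_locus <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_locus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ctg <- Biostrings::DNAStringSet(vapply(sim$contigs, `[[`, "", "sequence"))
  names(ctg) <- vapply(sim$contigs, `[[`, "", "id")
  Biostrings::writeXStringSet(ctg, file.path(dir, "contigs.fasta"))
  write_annotation(rbind(sim$truth$features, sim$truth$decoys),
                   file.path(dir, "truth.gff3"), format = "gff3",
                   assembly_length = nchar(sim$assembly))
  mat <- Biostrings::AAStringSet(sim$truth$mature_peptides)
  Biostrings::writeXStringSet(mat, file.path(dir, "mature.faa"))
  rp <- Biostrings::AAStringSet(sim$truth$receptor_proteins)
  Biostrings::writeXStringSet(rp, file.path(dir, "receptors.faa"))
  rc <- Biostrings::DNAStringSet(sim$truth$receptor_cdna)
  Biostrings::writeXStringSet(rc, file.path(dir, "receptors_cdna.fna"))
  utils::write.csv(sim$ct, file.path(dir, "ct.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(primer = c("fwd", "rev"),
                              sequence = unname(sim$truth$primers),
                              stringsAsFactors = FALSE),
                   file.path(dir, "primers.csv"), row.names = FALSE,
                   quote = FALSE)
  sp <- sim$spec
  keys <- setdiff(names(sp), c("layout", "fold_map", "receptor_tail_lens"))
  lines <- c(
    vapply(keys, function(k) paste0(k, "=", paste(sp[[k]], collapse = ",")), ""),
    paste0("receptor_tail_lens=", paste(names(sp$receptor_tail_lens),
                                        sp$receptor_tail_lens,
                                        sep = ":", collapse = ",")),
    paste0("fold_map=", paste(names(sp$fold_map), sp$fold_map,
                              sep = ":", collapse = ",")))
  writeLines(lines, file.path(dir, "config.txt"))
  invisible(dir)
}
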