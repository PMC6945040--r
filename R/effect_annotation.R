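AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter", X = "Xaa")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Translate a CDS (or prefix); trailing bases short of a codon are ignored.
translate_cds <- function(seq) {
  n <- (nchar(seq) %/% 3L) * 3L
  if (n == 0L) return("")
  as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(substr(seq, 1L, n)),
                          no.init.codon = TRUE, if.fuzzy.codon = "X")))
}

#' Construct a gene model
#'
#' A single-transcript gene model: exon and CDS intervals in genomic
#' coordinates (1-based inclusive, sorted, non-overlapping) plus the CDS
#' nucleotide sequence in transcript orientation (reverse-complemented
#' relative to the genome for minus-strand genes).
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data.frame of exon (start, end) pairs.
#' @param cds_intervals Two-column matrix or data.frame of CDS (start, end)
#'   pairs; must be contained in exons.
#' @param cds_sequence CDS nucleotide string in transcript orientation;
#'   length must equal the total CDS interval length, be divisible by 3,
#'   start with ATG and end with a stop codon.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds_intervals, cds_sequence) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.matrix(exons)[, 1:2, drop = FALSE]
  cds <- as.matrix(cds_intervals)[, 1:2, drop = FALSE]
  storage.mode(exons) <- "integer"; storage.mode(cds) <- "integer"
  check_intervals <- function(iv, what) {
    if (any(iv[, 2] < iv[, 1])) stop(what, " interval end < start")
    if (nrow(iv) > 1 && any(iv[-1, 1] <= iv[-nrow(iv), 2]))
      stop(what, " intervals must be sorted and non-overlapping")
  }
  check_intervals(exons, "exon"); check_intervals(cds, "CDS")
  cds_sequence <- toupper(cds_sequence)
  cds_len <- sum(cds[, 2] - cds[, 1] + 1L)
  if (nchar(cds_sequence) != cds_len)
    stop("cds_sequence length ", nchar(cds_sequence),
         " != total CDS interval length ", cds_len)
  if (cds_len %% 3L != 0L) stop("CDS length must be divisible by 3")
  if (substr(cds_sequence, 1, 3) != "ATG") stop("CDS must start with ATG")
  if (!substr(cds_sequence, cds_len - 2L, cds_len) %in% c("TAA", "TAG", "TGA"))
    stop("CDS must end with a stop codon")
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = unname(exons), cds_intervals = unname(cds),
                 cds_sequence = cds_sequence),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", x$gene_id, "on", x$chrom, x$strand,
      "|", nrow(x$exons), "exon(s),", nchar(x$cds_sequence), "bp CDS",
      "->", nchar(x$cds_sequence) / 3L - 1L, "aa\n")
  invisible(x)
}

gene_span <- function(gene) c(min(gene$exons[, 1]), max(gene$exons[, 2]))

in_intervals <- function(pos, iv) {
  any(pos >= iv[, 1] & pos <= iv[, 2])
}

# Genomic position -> 1-based CDS coordinate (transcript orientation),
# NA when outside the CDS.
genomic_to_cds <- function(gene, gpos) {
  iv <- gene$cds_intervals
  hit <- which(gpos >= iv[, 1] & gpos <= iv[, 2])
  if (length(hit) == 0) return(NA_integer_)
  lens <- iv[, 2] - iv[, 1] + 1L
  if (gene$strand == "+") {
    before <- if (hit > 1) sum(lens[seq_len(hit - 1)]) else 0L
    as.integer(before + (gpos - iv[hit, 1] + 1L))
  } else {
    after <- if (hit < nrow(iv)) sum(lens[seq(hit + 1, nrow(iv))]) else 0L
    as.integer(after + (iv[hit, 2] - gpos + 1L))
  }
}

# 1-based CDS coordinate -> genomic position.
cds_to_genomic <- function(gene, cpos) {
  iv <- gene$cds_intervals
  lens <- iv[, 2] - iv[, 1] + 1L
  if (cpos < 1L || cpos > sum(lens)) stop("CDS position ", cpos, " outside CDS")
  if (gene$strand == "+") {
    cum <- cumsum(lens)
    k <- which(cpos <= cum)[1]
    off <- cpos - (if (k > 1) cum[k - 1] else 0L)
    as.integer(iv[k, 1] + off - 1L)
  } else {
    cum <- cumsum(rev(lens))
    k_rev <- which(cpos <= cum)[1]
    k <- nrow(iv) - k_rev + 1L
    off <- cpos - (if (k_rev > 1) cum[k_rev - 1] else 0L)
    as.integer(iv[k, 2] - off + 1L)
  }
}

#' Read gene models from a TSV plus a CDS FASTA
#'
#' The TSV has columns `gene_id`, `chrom`, `strand`, `exons`,
#' `cds_intervals` (intervals encoded `start-end,start-end`), and
#' `cds_fasta_id` naming the record in the companion FASTA holding the CDS
#' sequence in transcript orientation.
#'
#' @param tsv_path Path to the gene table.
#' @param fasta_path Path to the CDS FASTA.
#' @return Named list of [gene_model()] objects.
#' @export
read_gene_models <- function(tsv_path, fasta_path) {
  df <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("gene_id", "chrom", "strand", "exons", "cds_intervals", "cds_fasta_id")
  if (!all(need %in% names(df)))
    stop("gene TSV must have columns: ", paste(need, collapse = ", "))
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  parse_iv <- function(s) {
    parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
    do.call(rbind, lapply(parts, function(p) as.integer(p)))
  }
  genes <- lapply(seq_len(nrow(df)), function(i) {
    fid <- df$cds_fasta_id[i]
    if (!fid %in% names(seqs))
      stop("CDS FASTA lacks record '", fid, "' for gene ", df$gene_id[i])
    gene_model(df$gene_id[i], df$chrom[i], df$strand[i],
               parse_iv(df$exons[i]), parse_iv(df$cds_intervals[i]),
               as.character(seqs[[fid]]))
  })
  stats::setNames(genes, df$gene_id)
}

#' Write gene models as a TSV plus a CDS FASTA
#'
#' @param genes List of [gene_model()] objects.
#' @param tsv_path,fasta_path Output paths.
#' @return `tsv_path`, invisibly.
#' @export
write_gene_models <- function(genes, tsv_path, fasta_path) {
  fmt_iv <- function(iv) paste(paste0(iv[, 1], "-", iv[, 2]), collapse = ",")
  df <- data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    chrom = vapply(genes, `[[`, "", "chrom"),
    strand = vapply(genes, `[[`, "", "strand"),
    exons = vapply(genes, function(g) fmt_iv(g$exons), ""),
    cds_intervals = vapply(genes, function(g) fmt_iv(g$cds_intervals), ""),
    cds_fasta_id = vapply(genes, `[[`, "", "gene_id"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  seqs <- Biostrings::DNAStringSet(vapply(genes, `[[`, "", "cds_sequence"))
  names(seqs) <- df$gene_id
  Biostrings::writeXStringSet(seqs, fasta_path, width = 70L)
  invisible(tsv_path)
}

# ---- impact classification -------------------------------------------------

# Decompose a VCF-style (ref, alt) pair into an event type. Insertions and
# deletions are expected left-anchored on a shared first base, VCF style.
variant_event <- function(ref, alt) {
  if (nchar(ref) == 1L && nchar(alt) == 1L)
    return(list(type = "snv"))
  if (nchar(alt) > nchar(ref) && substr(alt, 1, nchar(ref)) == ref)
    return(list(type = "ins", seq = substr(alt, nchar(ref) + 1L, nchar(alt))))
  if (nchar(ref) > nchar(alt) && substr(ref, 1, nchar(alt)) == alt)
    return(list(type = "del", seq = substr(ref, nchar(alt) + 1L, nchar(ref))))
  list(type = "complex")
}

impact_call <- function(category, reason, gene_id = NA_character_) {
  list(category = category, reason = reason, gene_id = gene_id)
}

#' Classify the coding impact of a variant
#'
#' A deliberately simplified effect classifier over single-transcript gene
#' models: a variant overlapping no gene (or intronic) is MODIFIER; within
#' an exon but outside the CDS it is LOW/noncoding; within the CDS, an
#' indel whose length change is not a multiple of 3 is HIGH/frameshift, an
#' in-frame indel is MODERATE/inframe_indel, an SNV creating a stop is
#' HIGH/stop_gain, destroying the start codon HIGH/start_lost, destroying
#' the stop codon HIGH/stop_lost, changing the amino acid
#' MODERATE/missense, and a silent SNV LOW/synonymous.
#'
#' @param chrom,pos,ref,alt The variant (VCF conventions: 1-based `pos`,
#'   indels left-anchored on a shared base).
#' @param genes List of [gene_model()] objects.
#' @return A list with `category` (HIGH/MODERATE/LOW/MODIFIER), `reason`
#'   (stable identifier) and `gene_id` (`NA` outside genes).
#' @export
classify_impact <- function(chrom, pos, ref, alt, genes) {
  pos <- as.integer(pos)
  hit <- NULL
  for (g in genes) {
    sp <- gene_span(g)
    if (g$chrom == chrom && pos >= sp[1] && pos <= sp[2]) { hit <- g; break }
  }
  if (is.null(hit)) return(impact_call("MODIFIER", "intergenic"))
  ev <- variant_event(ref, alt)
  in_cds <- function(p) in_intervals(p, hit$cds_intervals)
  in_ex <- function(p) in_intervals(p, hit$exons)

  if (ev$type == "snv") {
    if (!in_ex(pos)) return(impact_call("MODIFIER", "intronic", hit$gene_id))
    if (!in_cds(pos)) return(impact_call("LOW", "noncoding", hit$gene_id))
    cpos <- genomic_to_cds(hit, pos)
    alt_t <- if (hit$strand == "+") alt else revcomp(alt)
    codon_i <- (cpos - 1L) %/% 3L + 1L
    codon <- substr(hit$cds_sequence, 3L * codon_i - 2L, 3L * codon_i)
    off <- (cpos - 1L) %% 3L + 1L
    new_codon <- codon
    substr(new_codon, off, off) <- alt_t
    ref_aa <- translate_cds(codon)
    new_aa <- translate_cds(new_codon)
    if (codon_i == 1L && new_aa != "M")
      return(impact_call("HIGH", "start_lost", hit$gene_id))
    if (new_aa == ref_aa) return(impact_call("LOW", "synonymous", hit$gene_id))
    if (new_aa == "*") return(impact_call("HIGH", "stop_gain", hit$gene_id))
    if (ref_aa == "*") return(impact_call("HIGH", "stop_lost", hit$gene_id))
    return(impact_call("MODERATE", "missense", hit$gene_id))
  }

  if (ev$type %in% c("ins", "del")) {
    # insertion sits between pos and pos+1; a deletion removes pos+1 .. pos+len
    len <- nchar(ev$seq)
    span <- if (ev$type == "ins") c(pos, pos + 1L) else c(pos + 1L, pos + len)
    if (!in_ex(span[1]) && !in_ex(span[2]))
      return(impact_call("MODIFIER", "intronic", hit$gene_id))
    if (!(in_cds(span[1]) && in_cds(span[2])))
      return(impact_call("LOW", "noncoding", hit$gene_id))
    cpos <- vapply(span, function(p) genomic_to_cds(hit, p), integer(1))
    if (min(cpos) <= 3L)
      return(impact_call("HIGH", "start_lost", hit$gene_id))
    if (len %% 3L != 0L)
      return(impact_call("HIGH", "frameshift", hit$gene_id))
    return(impact_call("MODERATE", "inframe_indel", hit$gene_id))
  }

  impact_call("MODIFIER", "complex_unclassified", hit$gene_id)
}

# ---- HGVS-style consequence prediction -------------------------------------

aa3_string <- function(one_letter) {
  paste(AA3[strsplit(one_letter, "")[[1]]], collapse = "")
}

# HGVS most-3' rule: shift an insertion (rotating the inserted sequence) or
# a deletion window right while the edit is equivalent.
normalize_ins_3prime <- function(cds, p, seq) {
  while (p + 1L <= nchar(cds) &&
         substr(cds, p + 1L, p + 1L) == substr(seq, 1L, 1L)) {
    seq <- paste0(substr(seq, 2L, nchar(seq)), substr(seq, 1L, 1L))
    p <- p + 1L
  }
  list(p = p, seq = seq)
}

normalize_del_3prime <- function(cds, s, e) {
  while (e + 1L <= nchar(cds) &&
         substr(cds, s, s) == substr(cds, e + 1L, e + 1L)) {
    s <- s + 1L; e <- e + 1L
  }
  c(s, e)
}

protein_consequence <- function(cdna_notation, protein_notation,
                                truncated_length, full_length) {
  structure(list(cdna_notation = cdna_notation,
                 protein_notation = protein_notation,
                 truncated_length = truncated_length,
                 full_length = full_length,
                 retained_fraction = if (is.na(truncated_length)) NA_real_
                                     else truncated_length / full_length),
            class = "protein_consequence")
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat(x$cdna_notation, x$protein_notation, "\n")
  if (!is.na(x$truncated_length))
    cat("  truncated to", x$truncated_length, "of", x$full_length,
        sprintf("residues (%.1f%% retained)\n", 100 * x$retained_fraction))
  invisible(x)
}

#' Predict the protein consequence of a CDS insertion or deletion
#'
#' Applies the edit to the coding sequence, translates from the original
#' start codon, and names the outcome in HGVS style. For a frameshift the
#' notation is `p.(RefAA pos NewAA fsTer N)` where the first changed
#' residue counts as 1 and the premature stop as N, so the truncated
#' protein retains `pos + N - 2` residues. Insertions are 3'-normalized at
#' the nucleotide level before naming; the first changed residue is found
#' by comparing translations, so edits whose shifted frame initially
#' re-encodes the original residues are named at the first residue that
#' actually differs. Edits of length divisible by 3 yield an in-frame
#' consequence with no `fs` in the notation. A shifted frame with no
#' downstream stop yields `fsTer?` and an undefined truncated length.
#'
#' @param gene A [gene_model()], or a bare CDS nucleotide string.
#' @param cds_position Length-2 integer vector of 1-based CDS coordinates:
#'   for an insertion the flanking pair `c(p, p + 1)` (insert between), for
#'   a deletion the deleted range `c(start, end)`.
#' @param inserted Inserted nucleotide sequence (transcript orientation)
#'   for insertions; `NULL` for deletions.
#' @return A `protein_consequence`: HGVS-like c. and p. notations,
#'   `truncated_length` (residues before the premature stop, `NA` when no
#'   stop is found or the edit is in-frame), `full_length` (residues of the
#'   unedited protein, stop excluded) and `retained_fraction`.
#' @examples
#' frameshift_consequence("ATGAAAGGTAAATGA", c(4, 5), "T")  # p.(Lys2IlefsTer3)
#' @export
frameshift_consequence <- function(gene, cds_position, inserted = NULL) {
  cds <- if (inherits(gene, "gene_model")) gene$cds_sequence else toupper(gene)
  n <- nchar(cds)
  stopifnot(length(cds_position) == 2L)
  cds_position <- as.integer(cds_position)
  if (any(cds_position < 1L) || any(cds_position > n))
    stop("cds_position ", paste(cds_position, collapse = "_"),
         " outside CDS of length ", n)

  if (!is.null(inserted)) {
    inserted <- toupper(inserted)
    if (cds_position[2] != cds_position[1] + 1L)
      stop("insertion point must be a flanking pair c(p, p + 1)")
    norm <- normalize_ins_3prime(cds, cds_position[1], inserted)
    p <- norm$p; seq <- norm$seq
    cdna <- paste0("c.", p, "_", p + 1L, "ins", seq)
    edited <- paste0(substr(cds, 1L, p), seq, substr(cds, p + 1L, n))
    net <- nchar(seq)
  } else {
    se <- normalize_del_3prime(cds, cds_position[1], cds_position[2])
    cdna <- if (se[1] == se[2]) paste0("c.", se[1], "del")
            else paste0("c.", se[1], "_", se[2], "del")
    edited <- paste0(substr(cds, 1L, se[1] - 1L), substr(cds, se[2] + 1L, n))
    net <- -(se[2] - se[1] + 1L)
  }

  p0 <- translate_cds(cds)
  full_length <- nchar(p0) - 1L  # drop terminal stop
  pe_full <- translate_cds(edited)
  stop_at <- regexpr("*", pe_full, fixed = TRUE)
  pe <- if (stop_at > 0) substr(pe_full, 1L, stop_at) else pe_full

  if (net %% 3L == 0L)
    return(inframe_consequence(cdna, p0, pe, full_length))

  # first residue that actually differs between original and edited frames
  a0 <- strsplit(p0, "")[[1]]
  ae <- strsplit(pe, "")[[1]]
  m <- min(length(a0), length(ae))
  diff_i <- which(a0[seq_len(m)] != ae[seq_len(m)])
  first <- if (length(diff_i)) diff_i[1] else m + 1L
  if (first > length(ae)) {
    # no residue differs: the shifted frame re-encodes the original protein
    # (possible when the edit sits in the final codons)
    if (stop_at > 0)
      return(protein_consequence(cdna, "p.(=)", as.integer(stop_at - 1L),
                                 full_length))
    # matched throughout but the edited frame never terminates
    prot <- paste0("p.(Ter", full_length + 1L, "ext?)")
    return(protein_consequence(cdna, prot, NA_integer_, full_length))
  }
  ref_aa <- AA3[a0[first]]
  new_aa <- AA3[ae[first]]
  if (ae[first] == "*") {
    prot <- paste0("p.(", ref_aa, first, "Ter)")
    return(protein_consequence(cdna, prot, first - 1L, full_length))
  }
  if (stop_at > 0) {
    ter_n <- stop_at - first + 1L
    prot <- paste0("p.(", ref_aa, first, new_aa, "fsTer", ter_n, ")")
    return(protein_consequence(cdna, prot, as.integer(stop_at - 1L), full_length))
  }
  prot <- paste0("p.(", ref_aa, first, new_aa, "fsTer?)")
  protein_consequence(cdna, prot, NA_integer_, full_length)
}

# In-frame (length % 3 == 0) edits: name the protein-level difference
# without any fs notation.
inframe_consequence <- function(cdna, p0, pe, full_length) {
  a0 <- strsplit(sub("\\*$", "", p0), "")[[1]]
  ae <- strsplit(sub("\\*$", "", pe), "")[[1]]
  if (identical(a0, ae))
    return(protein_consequence(cdna, "p.(=)", NA_integer_, full_length))
  m <- min(length(a0), length(ae))
  lead <- 0L
  while (lead < m && a0[lead + 1L] == ae[lead + 1L]) lead <- lead + 1L
  trail <- 0L
  while (trail < m - lead &&
         a0[length(a0) - trail] == ae[length(ae) - trail]) trail <- trail + 1L
  core0 <- a0[seq.int(lead + 1L, length.out = length(a0) - lead - trail)]
  coree <- ae[seq.int(lead + 1L, length.out = length(ae) - lead - trail)]
  prot <- if (length(core0) == 0L) {
    # pure insertion between residues lead and lead + 1 (or before the
    # terminal stop when the insertion extends the protein)
    right <- if (lead < length(a0)) AA3[a0[lead + 1L]] else "Ter"
    paste0("p.(", AA3[a0[lead]], lead, "_", right, lead + 1L,
           "ins", aa3_string(paste(coree, collapse = "")), ")")
  } else if (length(coree) == 0L) {
    if (length(core0) == 1L)
      paste0("p.(", AA3[core0], lead + 1L, "del)")
    else
      paste0("p.(", AA3[core0[1]], lead + 1L, "_",
             AA3[core0[length(core0)]], lead + length(core0), "del)")
  } else {
    paste0("p.(", AA3[core0[1]], lead + 1L,
           if (length(core0) > 1) paste0("_", AA3[core0[length(core0)]],
                                         lead + length(core0)),
           "delins", aa3_string(paste(coree, collapse = "")), ")")
  }
  protein_consequence(cdna, prot, NA_integer_, full_length)
}

#' Truncation arithmetic from an HGVS fsTer notation
#'
#' For a frameshift `p.(AaaPosBbbfsTerN)` the premature stop lands at
#' protein residue `Pos + N - 1`, so the truncated protein retains
#' `(Pos - 1) + (N - 1)` residues.
#'
#' @param protein_notation HGVS-like p. frameshift string, with or without
#'   the `p.(...)` wrapper, e.g. `"Glu47GlyfsTer3"`.
#' @param full_length Predicted full protein length in residues.
#' @return A list with `truncated_length` (residues), `percent_retained`
#'   (exact), and `percent_retained_rounded` (nearest integer percent).
#' @examples
#' truncation_fraction("Glu47GlyfsTer3", 490)  # 48 residues, ~10%
#' @export
truncation_fraction <- function(protein_notation, full_length) {
  m <- regmatches(protein_notation,
                  regexec("([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})fsTer(\\d+)",
                          protein_notation))[[1]]
  if (length(m) == 0)
    stop("not a frameshift fsTer notation: '", protein_notation,
         "'; in-frame consequences carry no truncation arithmetic")
  pos <- as.integer(m[3]); ter_n <- as.integer(m[5])
  truncated <- (pos - 1L) + (ter_n - 1L)
  pct <- 100 * truncated / full_length
  list(truncated_length = truncated,
       percent_retained = pct,
       percent_retained_rounded = as.integer(round(pct)))
}

# ---- per-variant annotation ------------------------------------------------

#' Annotate a variant set with impact and consequence calls
#'
#' Runs [classify_impact()] on every variant and, for coding indels, the
#' consequence predictor, yielding one annotation row per variant.
#'
#' @param variants A [variant_set()].
#' @param genes List of [gene_model()] objects.
#' @return data.frame with columns `gene`, `category`, `reason`,
#'   `cdna_notation`, `protein_notation`, `retained_fraction` (aligned with
#'   the variant rows).
#' @export
annotate_variants <- function(variants, genes) {
  n <- n_variants(variants)
  out <- data.frame(gene = rep(NA_character_, n),
                    category = rep(NA_character_, n),
                    reason = rep(NA_character_, n),
                    cdna_notation = rep(NA_character_, n),
                    protein_notation = rep(NA_character_, n),
                    retained_fraction = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  gene_by_id <- stats::setNames(genes, vapply(genes, `[[`, "", "gene_id"))
  for (i in seq_len(n)) {
    s <- variants$sites[i, ]
    ic <- classify_impact(s$chrom, s$pos, s$ref, s$alt, genes)
    out$gene[i] <- ic$gene_id
    out$category[i] <- ic$category
    out$reason[i] <- ic$reason
    if (ic$reason %in% c("frameshift", "inframe_indel")) {
      g <- gene_by_id[[ic$gene_id]]
      ev <- variant_event(s$ref, s$alt)
      cons <- tryCatch(indel_consequence(g, s$pos, ev), error = function(e) NULL)
      if (!is.null(cons)) {
        out$cdna_notation[i] <- cons$cdna_notation
        out$protein_notation[i] <- cons$protein_notation
        out$retained_fraction[i] <- cons$retained_fraction
      }
    } else if (ic$reason %in% c("missense", "synonymous", "stop_gain", "stop_lost")) {
      g <- gene_by_id[[ic$gene_id]]
      out$cdna_notation[i] <- snv_cdna_notation(g, s$pos, s$ref, s$alt)
    }
  }
  out
}

snv_cdna_notation <- function(gene, pos, ref, alt) {
  cpos <- genomic_to_cds(gene, pos)
  if (is.na(cpos)) return(NA_character_)
  if (gene$strand == "-") { ref <- revcomp(ref); alt <- revcomp(alt) }
  paste0("c.", cpos, ref, ">", alt)
}

# Map a genomic VCF-style indel into CDS coordinates and run the
# consequence predictor. The insertion anchor base is `pos`; on the minus
# strand the transcript-orientation insertion point flips.
indel_consequence <- function(gene, pos, ev) {
  pos <- as.integer(pos)
  if (ev$type == "ins") {
    if (gene$strand == "+") {
      p <- genomic_to_cds(gene, pos)
      seq <- ev$seq
    } else {
      p <- genomic_to_cds(gene, pos + 1L)
      seq <- revcomp(ev$seq)
    }
    frameshift_consequence(gene, c(p, p + 1L), seq)
  } else if (ev$type == "del") {
    g_range <- c(pos + 1L, pos + nchar(ev$seq))
    c_range <- sort(vapply(g_range, function(p) genomic_to_cds(gene, p), integer(1)))
    frameshift_consequence(gene, c_range)
  } else {
    stop("not an indel event")
  }
}

#' Write an annotated VCF
#'
#' Writes the variants with an `MSQ` INFO field
#' `gene|category|reason|c.notation|p.notation` appended to each record.
#'
#' @param variants A [variant_set()].
#' @param annotations Annotation data.frame from [annotate_variants()].
#' @param pedigree The matching [pedigree_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated_vcf <- function(variants, annotations, pedigree, path) {
  write_pedigree_vcf(variants, pedigree, path)
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  msq_hdr <- paste0("##INFO=<ID=MSQ,Number=1,Type=String,Description=",
                    "\"Simplified consequence: gene|category|reason|cdna|protein\">")
  hdr <- append(lines[is_hdr], msq_hdr, after = sum(is_hdr) - 1L)
  body <- lines[!is_hdr]
  if (length(body)) {
    na_dot <- function(x) ifelse(is.na(x), ".", x)
    msq <- paste(na_dot(annotations$gene), na_dot(annotations$category),
                 na_dot(annotations$reason), na_dot(annotations$cdna_notation),
                 na_dot(annotations$protein_notation), sep = "|")
    parts <- strsplit(body, "\t", fixed = TRUE)
    body <- vapply(seq_along(parts), function(i) {
      p <- parts[[i]]
      p[8] <- if (p[8] == ".") paste0("MSQ=", msq[i])
              else paste0(p[8], ";MSQ=", msq[i])
      paste(p, collapse = "\t")
    }, character(1))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
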