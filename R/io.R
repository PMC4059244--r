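## Interchange formats: genotype CSV, SNP panel and band TSV, lesion VCF,
## gene-model GFF3 (+FASTA), JSON mapping reports and run manifests.
## On disk VCF/GFF3 are 1-based inclusive; in memory everything is 0-based
## half-open. Conversion happens only here.

PHENOTYPE_TOKENS <- c("mutant", "wild_type", "weak", "unknown")
CALL_TOKENS <- c("MUT", "MAP", "FAIL")

#' Stable short hash of a configuration
#'
#' FNV-1a 32-bit over a canonical JSON rendering; echoed in genotype-table
#' headers and manifests so outputs can be matched to the config that
#' produced them.
#'
#' @param config A [sim_config()] (or any list-like config).
#' @return Eight-character lowercase hex string.
#' @export
config_hash <- function(config) {
  s <- as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                     null = "null"))
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b %% 256)
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  # h is a double in [0, 2^32); format the two 16-bit halves separately
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write / read the genotype table (CSV)
#'
#' Columns: `line_id`, `phenotype`, then one column per panel marker with
#' values `MUT`/`MAP`/`FAIL`. A `#`-prefixed header records the seed and a
#' config hash. Unknown call tokens read back as `FAIL`, unknown phenotype
#' tokens as `unknown`, each with a warning naming the count.
#'
#' @param cohort An `f2_cohort`.
#' @param panel The matching [snp_panel()].
#' @param path Output file.
#' @param config Optional [sim_config()] echoed in the header.
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(cohort, panel, path, config = NULL) {
  df <- cbind(cohort$lines, as.data.frame(cohort$calls,
                                          stringsAsFactors = FALSE))
  hdr <- c("# mosaicmap genotype table",
           sprintf("# seed=%s config_hash=%s",
                   cohort$seed %||% NA,
                   if (is.null(config)) "none" else config_hash(config)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotype_csv
#' @export
read_genotype_table <- function(path, panel) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!all(c("line_id", "phenotype") %in% names(df)))
    stop("genotype table must have line_id and phenotype columns: ", path)
  if (anyDuplicated(df$line_id))
    stop("duplicated line_id in genotype table: ",
         df$line_id[duplicated(df$line_id)][1])
  snp_cols <- setdiff(names(df), c("line_id", "phenotype"))
  missing <- setdiff(panel$loci$snp_id, snp_cols)
  extra <- setdiff(snp_cols, panel$loci$snp_id)
  if (length(missing) || length(extra))
    stop("genotype columns do not match the panel (missing: ",
         paste(missing, collapse = ","), "; unexpected: ",
         paste(extra, collapse = ","), ")")
  calls <- as.matrix(df[, panel$loci$snp_id, drop = FALSE])
  rownames(calls) <- df$line_id
  bad <- !(calls %in% CALL_TOKENS)
  if (any(bad)) {
    warning(sum(bad), " unrecognized genotype token(s) set to FAIL")
    calls[bad] <- "FAIL"
  }
  ph <- df$phenotype
  badp <- !(ph %in% PHENOTYPE_TOKENS)
  if (any(badp)) {
    warning(sum(badp), " unrecognized phenotype token(s) set to unknown")
    ph[badp] <- "unknown"
  }
  structure(list(lines = data.frame(line_id = df$line_id, phenotype = ph,
                                    stringsAsFactors = FALSE),
                 calls = calls, truth = NULL, seed = NA_integer_),
            class = "f2_cohort")
}

#' Write / read a SNP panel (TSV)
#'
#' @param panel An [snp_panel()].
#' @param path File path.
#' @return `path` / an `snp_panel`.
#' @export
write_panel_tsv <- function(panel, path) {
  df <- panel$loci
  df$anchor <- ""
  df$anchor[match(panel$anchors[["distal"]], df$snp_id)] <- "distal"
  df$anchor[match(panel$anchors[["proximal"]], df$snp_id)] <- "proximal"
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "position_bp", "allele_mut", "allele_map")
  if (!all(need %in% names(df)))
    stop("panel TSV must have columns ", paste(need, collapse = ", "))
  if ("anchor" %in% names(df) && any(df$anchor == "distal") &&
      any(df$anchor == "proximal")) {
    snp_panel(df[setdiff(names(df), "anchor")],
              distal_anchor = df$snp_id[df$anchor == "distal"][1],
              proximal_anchor = df$snp_id[df$anchor == "proximal"][1])
  } else snp_panel(df)
}

#' Read / write a cytological band table (TSV)
#'
#' Columns `band`, `start_bp`, `end_bp` (half-open, tiling the arm).
#'
#' @param path File path.
#' @param band_table Data.frame as stored in `arm$band_table`.
#' @return A band-table data.frame / `path`.
#' @export
read_band_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("band", "start_bp", "end_bp") %in% names(df)))
    stop("band table TSV must have columns band, start_bp, end_bp")
  df
}

#' @rdname read_band_table
#' @export
write_band_table <- function(band_table, path) {
  utils::write.table(band_table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a lesion list as a minimal VCF
#'
#' Plain-text VCF v4.2, one contig (the arm). Internally 0-based lesions
#' become 1-based records; deletions and insertions use a preceding anchor
#' base (`N` when the true base is unknown), and insertions whose `alt` is
#' an element label rather than sequence are written as symbolic
#' `<INS:ME:label>` ALTs.
#'
#' @param lesions Lesion data.frame.
#' @param arm The [arm_model()] (contig name and length).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_lesions_vcf <- function(lesions, arm, path) {
  rec <- vapply(seq_len(nrow(lesions)), function(i) {
    l <- lesions[i, ]
    if (l$kind == "snv") {
      pos <- l$position_bp + 1; ref <- l$ref; alt <- l$alt
    } else if (l$kind == "deletion") {
      if (l$position_bp < 1) stop("cannot anchor a deletion at position 0")
      pos <- l$position_bp; ref <- paste0("N", l$ref); alt <- "N"
    } else {
      if (l$position_bp < 1) stop("cannot anchor an insertion at position 0")
      pos <- l$position_bp
      if (grepl("^[ACGTNacgtn]+$", l$alt)) {
        ref <- "N"; alt <- paste0("N", l$alt)
      } else {
        ref <- "N"; alt <- sprintf("<INS:ME:%s>", l$alt)
      }
    }
    sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", arm$name, as.integer(pos),
            l$id, ref, alt)
  }, character(1))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=mosaicmap",
               sprintf("##contig=<ID=%s,length=%d>", arm$name,
                       as.integer(arm$length_bp)),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               rec), path)
  invisible(path)
}

#' Read a lesion list from VCF
#'
#' Accepts the minimal subset written by [write_lesions_vcf()] as well as
#' any VCF whose single contig matches the arm name. Multi-allelic records
#' are split with a warning; symbolic `<INS...>` ALTs become insertions
#' carrying the element label.
#'
#' @param path VCF file.
#' @param arm The [arm_model()] the coordinates refer to.
#' @return A lesion data.frame (see [lesion_table()]).
#' @export
read_lesions_vcf <- function(path, arm) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm)  # single record drops to a vector
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(lesion_table(character(0), numeric(0)))
  if (!all(fix$CHROM == arm$name))
    stop("VCF contig(s) ", paste(unique(fix$CHROM), collapse = ","),
         " do not match arm ", arm$name)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) split")
    fix <- do.call(rbind, lapply(seq_len(nrow(fix)), function(i) {
      alts <- strsplit(fix$ALT[i], ",")[[1]]
      out <- fix[rep(i, length(alts)), , drop = FALSE]
      out$ALT <- alts
      if (length(alts) > 1L) out$ID <- paste0(out$ID, ".", seq_along(alts))
      out
    }))
  }
  pos1 <- as.numeric(fix$POS)
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                sprintf("vcf_%03d", seq_len(nrow(fix))), fix$ID)
  one <- function(i) {
    ref <- fix$REF[i]; alt <- fix$ALT[i]
    if (grepl("^<INS", alt)) {
      label <- sub("^<(.*)>$", "\\1", alt)
      label <- utils::tail(strsplit(label, ":")[[1]], 1L)
      data.frame(id = ids[i], position_bp = pos1[i], kind = "insertion",
                 ref = "", alt = label, stringsAsFactors = FALSE)
    } else if (nchar(ref) == 1L && nchar(alt) == 1L) {
      data.frame(id = ids[i], position_bp = pos1[i] - 1, kind = "snv",
                 ref = ref, alt = alt, stringsAsFactors = FALSE)
    } else if (nchar(ref) > nchar(alt)) {
      data.frame(id = ids[i], position_bp = pos1[i] - 1 + nchar(alt),
                 kind = "deletion",
                 ref = substr(ref, nchar(alt) + 1L, nchar(ref)), alt = "",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id = ids[i], position_bp = pos1[i] - 1 + nchar(ref),
                 kind = "insertion", ref = "",
                 alt = substr(alt, nchar(ref) + 1L, nchar(alt)),
                 stringsAsFactors = FALSE)
    }
  }
  les <- do.call(rbind, lapply(seq_len(nrow(fix)), one))
  les[order(les$position_bp), , drop = FALSE]
}

#' Write / read gene models as GFF3 (with optional FASTA)
#'
#' Gene, mRNA, exon and CDS features with ID/Parent attributes, 1-based
#' inclusive on disk. Sequences are carried in a companion FASTA of the
#' whole arm (intergenic sequence written as `N`); codon-level effect
#' classification needs that companion.
#'
#' @param genes A [gene_model()].
#' @param arm The [arm_model()].
#' @param path GFF3 output file.
#' @return `path` / a `gene_model`.
#' @export
write_gene_model_gff3 <- function(genes, arm, path) {
  feats <- list()
  for (g in genes$genes) {
    tid <- paste0(g$gene_id, ".t1")
    cds <- gene_cds_intervals(g)
    w <- cds[, 2] - cds[, 1]
    tr_order <- if (g$strand == "+") seq_len(nrow(cds))
                else rev(seq_len(nrow(cds)))
    phase <- integer(nrow(cds))
    phase[tr_order] <- (3 - cumsum(c(0, w[tr_order][-nrow(cds)])) %% 3) %% 3
    feats[[length(feats) + 1L]] <- data.frame(
      start = c(g$start, g$start, g$exons[, 1], cds[, 1]) + 1,
      end = c(g$end, g$end, g$exons[, 2], cds[, 2]),
      type = c("gene", "mRNA", rep("exon", nrow(g$exons)),
               rep("CDS", nrow(cds))),
      ID = c(g$gene_id, tid,
             paste0(tid, ".exon", seq_len(nrow(g$exons))),
             paste0(tid, ".cds", seq_len(nrow(cds)))),
      Parent = c(NA, g$gene_id, rep(tid, nrow(g$exons) + nrow(cds))),
      phase = c(rep(NA_integer_, 2L + nrow(g$exons)), phase),
      strand = g$strand, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    seqnames = arm$name,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand, type = df$type, ID = df$ID, Parent = df$Parent,
    phase = df$phase)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gene_model_gff3
#' @param fasta Optional FASTA of the arm for sequence attachment.
#' @export
read_gene_models_gff3 <- function(path, fasta = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(S4Vectors::mcols(gr)$Parent, function(p)
    if (length(p) == 0L) NA_character_ else as.character(p[1]), character(1))
  arm_seq <- if (!is.null(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    as.character(ss[[1]])
  } else NULL
  genes <- lapply(df$ID[df$type == "gene"], function(gid) {
    mr <- df$ID[df$type == "mRNA" & df$Parent == gid][1]
    ex <- df[df$type == "exon" & df$Parent == mr, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    cds <- df[df$type == "CDS" & df$Parent == mr, , drop = FALSE]
    strand <- as.character(df$strand[df$type == "gene" & df$ID == gid][1])
    span <- c(min(ex$start) - 1, max(ex$end))
    make_gene(gid, strand, cbind(ex$start - 1, ex$end),
              cds_start_bp = min(cds$start) - 1, cds_end_bp = max(cds$end),
              seq = if (!is.null(arm_seq))
                substr(arm_seq, span[1] + 1, span[2]) else NULL)
  })
  gene_model(genes)
}

#' Write the arm sequence implied by a gene model as FASTA
#'
#' Intergenic positions are written as `N`. Intended for small arms (test
#' fixtures and worked examples); the string is materialized in memory.
#'
#' @param genes A [gene_model()] with sequences.
#' @param arm The [arm_model()].
#' @param path FASTA output file.
#' @return `path`, invisibly.
#' @export
write_arm_fasta <- function(genes, arm, path) {
  s <- strrep("N", arm$length_bp)
  for (g in genes$genes)
    if (!is.null(g$seq)) substr(s, g$start + 1, g$end) <- g$seq
  writeLines(c(sprintf(">%s", arm$name),
               substring(s, seq(1, nchar(s), 70),
                         pmin(seq(1, nchar(s), 70) + 69, nchar(s)))), path)
  invisible(path)
}

#' Serialize / restore a simulation configuration (flat key=value text)
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `path` / a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  kv <- c(lesion_rate_per_bp = config$lesion_rate_per_bp,
          n_f2_lines = config$n_f2_lines,
          crossover_mean = config$crossover_mean %||% NA,
          phenotyping_error = config$phenotyping_error,
          genotype_fail_rate = config$genotype_fail_rate,
          genotype_miscall_rate = config$genotype_miscall_rate,
          seed = config$seed,
          two_locus_distal_bp = config$two_locus$distal_bp %||% NA,
          two_locus_proximal_bp = config$two_locus$proximal_bp %||% NA)
  writeLines(c(sprintf("# mosaicmap sim_config hash=%s", config_hash(config)),
               sprintf("%s=%s", names(kv), format(kv, digits = 15,
                                                  trim = TRUE))), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  ln <- grep("^[^#]", readLines(path), value = TRUE)
  kv <- strsplit(ln, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  num <- function(k) {
    x <- suppressWarnings(as.numeric(vals[[k]]))
    if (is.na(x)) NULL else x
  }
  tl <- if (!is.null(num("two_locus_distal_bp")))
    list(distal_bp = num("two_locus_distal_bp"),
         proximal_bp = num("two_locus_proximal_bp")) else NULL
  sim_config(lesion_rate_per_bp = num("lesion_rate_per_bp"),
             n_f2_lines = num("n_f2_lines"),
             crossover_mean = num("crossover_mean"),
             phenotyping_error = num("phenotyping_error"),
             genotype_fail_rate = num("genotype_fail_rate"),
             genotype_miscall_rate = num("genotype_miscall_rate"),
             seed = num("seed"), two_locus = tl)
}

#' Write a run manifest (JSON)
#'
#' Records the config, its hash, the seed, package version and input-file
#' checksums so that any randomized run can be reproduced from the
#' manifest alone.
#'
#' @param path Output JSON file.
#' @param config A [sim_config()] (or any list-like config).
#' @param seed The seed in force.
#' @param inputs Character vector of input file paths to checksum.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, inputs = character(0)) {
  md5 <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(
    list(tool = "mosaicmap",
         version = as.character(utils::packageVersion("mosaicmap")),
         seed = seed, config = unclass(config),
         config_hash = config_hash(config), input_md5 = md5),
    path, auto_unbox = TRUE, null = "null", pretty = TRUE, digits = NA)
  invisible(path)
}

#' Mapping report output
#'
#' @param result A `mapped_result`.
#' @param arm The [arm_model()] (for band coordinates in the JSON).
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_mapping_report <- function(result, arm, path) {
  jsonlite::write_json(
    list(status = result$status,
         interval_bp = as.list(result$interval_bp),
         interval_bands = as.list(result$interval_bands),
         direction = result$direction,
         group_counts = lapply(result$group_counts, as.list),
         conflicts = result$conflicts,
         remaining_informative = result$remaining_informative,
         n_informative_recombinants = result$n_informative_recombinants,
         exclusions = lapply(result$exclusions, function(e)
           list(rule = e$rule,
                intervals = apply(e$intervals, 1, function(r)
                  list(start_bp = r[[1]], end_bp = r[[2]]),
                  simplify = FALSE)))),
    path, auto_unbox = TRUE, null = "null", pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mapping_report
#' @export
format_mapping_summary <- function(result) {
  gc <- result$group_counts
  out <- c(
    sprintf("exclusion mapping on arm %s: status %s",
            result$arm_name %||% "?", result$status),
    sprintf("  groups (mutant/total): 1 distal-mut %d/%d; 2 proximal-mut %d/%d; 3 nonrecombinant %d/%d",
            gc$group1[["mutant"]], gc$group1[["total"]],
            gc$group2[["mutant"]], gc$group2[["total"]],
            gc$group3[["mutant"]], gc$group3[["total"]]),
    sprintf("  stage-1 direction: lesion nearer the %s anchor",
            result$direction))
  if (!is.null(result$interval_bp))
    out <- c(out, sprintf(
      "  interval: %s-%s (%.0f-%.0f bp, %.2f Mb)",
      result$interval_bands[["left"]], result$interval_bands[["right"]],
      result$interval_bp[["start_bp"]], result$interval_bp[["end_bp"]],
      (result$interval_bp[["end_bp"]] - result$interval_bp[["start_bp"]]) / 1e6))
  c(out,
    sprintf("  %d recombinant(s) retain breakpoints inside the interval; %d conflict(s)",
            length(result$remaining_informative), length(result$conflicts)))
}
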