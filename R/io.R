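# File formats: TSV tables for trajectories/assays/landscapes/expression,
# GFF3 for the toy annotation, minimal VCF for variant calls, BED-like TSV
# for CNV segments (converted to 1-based inclusive on ingest), JSON for the
# simulator truth and genotype trees, YAML/JSON for configuration.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, ...)
}

#' Write / read allele-frequency trajectories
#'
#' TSV columns: mutation_id, locus, generation, frequency,
#' final_deepseq_freq.
#' @param trajs trajectory data.frame ([observe_allele_frequencies()] output).
#' @param path file path.
#' @export
write_trajectories_tsv <- function(trajs, path) write_tsv(trajs, path)

#' @rdname write_trajectories_tsv
#' @export
read_trajectories_tsv <- function(path) {
  d <- read_tsv(path)
  req <- c("mutation_id", "locus", "generation", "frequency",
           "final_deepseq_freq")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("trajectory table missing columns: ", paste(miss, collapse = ", "))
  d
}

#' Write / read competition-assay tables
#'
#' Long TSV with columns assay_id, generation and either ratio or
#' count_evolved + count_reference.
#' @param assays assay data.frame; @param path file path.
#' @export
write_competition_tsv <- function(assays, path) write_tsv(assays, path)

#' @rdname write_competition_tsv
#' @export
read_competition_tsv <- function(path) {
  d <- read_tsv(path)
  if (!all(c("assay_id", "generation") %in% names(d)))
    stop("competition table needs assay_id and generation columns")
  if (!("ratio" %in% names(d)) &&
      !all(c("count_evolved", "count_reference") %in% names(d)))
    stop("competition table needs ratio or count_evolved/count_reference")
  d
}

#' Write / read fitness-landscape tables
#'
#' TSV columns: genotype (bitstring), s, se.
#' @param landscape a \code{fitness_landscape}; @param path file path.
#' @export
write_landscape_tsv <- function(landscape, path) {
  write_tsv(landscape$table, path)
}

#' @rdname write_landscape_tsv
#' @param loci locus names (bit order) for reconstruction.
#' @export
read_landscape_tsv <- function(path, loci) {
  d <- read_tsv(path, colClasses = c(genotype = "character"))
  fitness_landscape(loci, d)
}

#' Write / read an expression matrix
#'
#' TSV with a \code{gene} column followed by one column per sample.
#' @param expr gene x sample matrix; @param path file path.
#' @export
write_expression_tsv <- function(expr, path) {
  write_tsv(data.frame(gene = rownames(expr), expr, check.names = FALSE),
            path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  d <- read_tsv(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene
  m
}

#' Serialize simulator truth to JSON
#'
#' Genotype tree plus the full frequency matrix and the seed, sufficient to
#' reconstruct every derived quantity.
#' @param result an \code{evolution_result}; @param path file path.
#' @export
write_evolution_json <- function(result, path) {
  obj <- list(seed = result$config$seed,
              sample_generations = result$config$sample_generations,
              tree = result$tree,
              loci = lapply(result$loci, identity),
              generations = as.integer(colnames(result$freq)),
              frequency_matrix = unname(apply(result$freq, 1, identity,
                                              simplify = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a genotype tree to JSON / Newick
#'
#' @param tree a \code{genotype_tree}; @param path file path.
#' @export
write_tree_json <- function(tree, path) {
  obj <- list(nodes = tree$nodes,
              generations = tree$generations,
              raw_frequencies = unname(apply(tree$raw, 1, identity,
                                             simplify = FALSE)),
              node_ids = rownames(tree$raw),
              members = tree$members,
              containment_tol = tree$containment_tol)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  # jsonlite simplifies equal-length rows to a matrix; ragged stays a list
  raw <- obj$raw_frequencies
  if (is.list(raw)) raw <- do.call(rbind, raw)
  rownames(raw) <- obj$node_ids
  colnames(raw) <- as.character(obj$generations)
  members <- lapply(obj$members, function(m) as.character(unlist(m)))
  nodes <- as.data.frame(obj$nodes)
  # JSON omits NA fields (the root's parent); restore layout and types
  if (is.null(nodes$parent)) nodes$parent <- NA_character_
  nodes <- nodes[, c("id", "parent", "depth")]
  nodes$depth <- as.integer(nodes$depth)
  structure(list(nodes = nodes, raw = raw,
                 members = members, generations = obj$generations,
                 containment_tol = obj$containment_tol),
            class = "genotype_tree")
}

#' @rdname write_tree_json
#' @return \code{tree_to_newick}: a Newick string with node labels
#'   annotated by member mutations.
#' @export
tree_to_newick <- function(tree) {
  lab <- function(id) {
    mem <- tree$members[[id]]
    if (length(mem)) paste0(id, "_", paste(mem, collapse = "-")) else id
  }
  rec <- function(id) {
    kids <- tree$nodes$id[!is.na(tree$nodes$parent) & tree$nodes$parent == id]
    if (!length(kids)) return(lab(id))
    paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","),
           ")", lab(id))
  }
  paste0(rec("root"), ";")
}

#' Read variant calls from a minimal VCF
#'
#' Accepts uncompressed single-sample VCFs carrying read-depth evidence in
#' INFO (DP = total depth, AD = ref,alt depths). Extra INFO keys CP (caller
#' p-value), BQ20/BQ30 (tier presence, 0/1) are honored when present.
#'
#' @param path VCF file.
#' @param sample_id,sample_kind attached to every call.
#' @return data.frame in the package's variant-call layout.
#' @export
read_vcf_calls <- function(path, sample_id = NA_character_,
                           sample_kind = "population") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  ad <- vcfR::extract.info(v, "AD")
  if (all(is.na(dp)) || all(is.na(ad)))
    stop("VCF lacks required INFO fields: DP and AD")
  alt_count <- vapply(strsplit(ad, ","), function(x)
    as.numeric(x[length(x)]), numeric(1))
  cp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "CP")))
  bq20 <- vcfR::extract.info(v, "BQ20")
  bq30 <- vcfR::extract.info(v, "BQ30")
  data.frame(chromosome = fix$CHROM,
             position = as.integer(fix$POS),
             ref = fix$REF, alt = fix$ALT,
             alt_count = alt_count, total_count = dp,
             caller_p = cp,
             bq20 = if (all(is.na(bq20))) TRUE else bq20 == "1",
             bq30 = if (all(is.na(bq30))) TRUE else bq30 == "1",
             sample_id = sample_id, sample_kind = sample_kind,
             stringsAsFactors = FALSE)
}

#' Read CNV segments from a BED-like file
#'
#' BED is 0-based half-open; coordinates are converted to the package's
#' 1-based inclusive convention on ingest (a record 0..10000 becomes
#' 1..10000, length 10000). Column 4 (or a \code{log2_ratio} header) carries
#' the mean log2 ratio.
#'
#' @param path BED-like TSV (chrom, start, end, log2_ratio).
#' @export
read_bed_segments <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("start", first, ignore.case = TRUE)
  d <- utils::read.table(path, sep = "\t", header = has_header,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 4)
    stop("BED-like segment file needs 4 columns: chrom, start, end, log2_ratio")
  names(d)[1:4] <- c("chromosome", "start", "end", "log2_ratio")
  bad <- which(d$end <= d$start)
  if (length(bad))
    stop("malformed segment at line ", bad[1] + has_header,
         ": end <= start")
  d$start <- d$start + 1L  # 0-based half-open -> 1-based inclusive
  d[, 1:4]
}

#' Write / read the toy annotation
#'
#' Gene intervals as GFF3 (via rtracklayer) plus a two-column term TSV.
#' @param annotation an \code{annotation_set}.
#' @param gff_path,terms_path output paths.
#' @export
write_annotation_gff <- function(annotation, gff_path, terms_path = NULL) {
  g <- annotation$genes
  g$type <- "gene"
  g$ID <- g$gene_id
  rtracklayer::export(g, gff_path, format = "gff3")
  if (!is.null(terms_path)) write_tsv(annotation$terms, terms_path)
  invisible(gff_path)
}

#' @rdname write_annotation_gff
#' @param genome_length chromosome length (recorded, not stored in GFF).
#' @export
read_annotation_gff <- function(gff_path, terms_path = NULL,
                                genome_length = NA_real_) {
  g <- rtracklayer::import(gff_path, format = "gff3")
  if (is.null(g$gene_id)) g$gene_id <- g$ID
  terms <- if (!is.null(terms_path)) read_tsv(terms_path) else
    data.frame(term = character(0), gene = character(0))
  structure(list(genes = g, terms = terms,
                 genome_length = if (is.na(genome_length))
                   max(GenomicRanges::end(g)) else genome_length),
            class = "annotation_set")
}
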