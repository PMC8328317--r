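# Atomic write: write to a temp file in the same directory, then rename.
atomic_write <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    file.remove(tmp)
    stop("could not write ", path)
  }
  invisible(path)
}

atomic_write_table <- function(df, path, ...) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                     ...)
  if (!file.rename(tmp, path)) {
    file.remove(tmp)
    stop("could not write ", path)
  }
  invisible(path)
}

#' Write a cohort's genotypes (and allele depths) as VCF 4.2
#'
#' Emits a plain-text VCF with phased `GT` from the haplotype panel and,
#' when read counts are supplied, an `AD` FORMAT field. Positions are
#' 1-based as VCF requires.
#'
#' @param panel a `haplotype_panel`.
#' @param path output file.
#' @param counts optional `site_read_counts` for `AD`.
#' @param chrom chromosome label (default `"6"`).
#' @return the path, invisibly.
#' @export
write_vcf <- function(panel, path, counts = NULL, chrom = "6") {
  H <- panel$haplotypes
  n <- length(panel$individuals)
  m <- ncol(H)
  has_ad <- !is.null(counts)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", chrom),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_ad)
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$individuals), collapse = "\t"))
  h1 <- H[seq(1, 2 * n, 2), , drop = FALSE]
  h2 <- H[seq(2, 2 * n, 2), , drop = FALSE]
  fmt <- if (has_ad) "GT:AD" else "GT"
  body <- vapply(seq_len(m), function(s) {
    gt <- paste0(h1[, s], "|", h2[, s])
    if (has_ad)
      gt <- paste0(gt, ":", counts$ref[, s], ",", counts$alt[, s])
    paste(c(chrom, panel$positions[s], sprintf("snp%05d", s), "A", "C",
            ".", "PASS", ".", fmt, gt), collapse = "\t")
  }, "")
  atomic_write(c(header, body), path)
}

#' Read genotypes (and allele depths) from a VCF
#'
#' Parses a VCF 4.2 via `vcfR` and returns dosage and phased haplotype
#' matrices plus `AD` depths when present. Missing genotypes (`./.`)
#' become `NA`, never 0. Multi-allelic records are rejected or dropped
#' according to `multiallelic`.
#'
#' @param path VCF file.
#' @param multiallelic `"error"` (default) or `"drop"`.
#' @return list with `positions`, `variants` (ids), `dosages`
#'   (individuals x sites), `haplotypes` (2 rows per individual when
#'   phased, else `NULL`), `ref_depth`/`alt_depth` (or `NULL`).
#' @export
read_vcf_genotypes <- function(path, multiallelic = c("error", "drop")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  as_fix <- function(vv) {
    f <- vcfR::getFIX(vv)
    if (is.null(dim(f))) f <- t(as.matrix(f))   # single-record VCF
    f
  }
  fix <- as_fix(v)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    if (multiallelic == "error")
      stop("multi-allelic record(s) at line(s): ",
           paste(which(multi), collapse = ", "))
    v <- v[!multi, ]
    fix <- as_fix(v)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  phased <- all(grepl("\\||\\.", gt[!is.na(gt)]))
  a1 <- matrix(suppressWarnings(as.integer(substr(gt, 1, 1))), nrow(gt))
  a2 <- matrix(suppressWarnings(as.integer(substr(gt, 3, 3))), nrow(gt))
  dos <- t(a1 + a2)
  rownames(dos) <- colnames(gt)
  colnames(dos) <- rownames(gt)
  haps <- NULL
  if (phased) {
    n <- ncol(gt)
    haps <- matrix(NA_integer_, 2 * n, nrow(gt))
    haps[seq(1, 2 * n, 2), ] <- t(a1)
    haps[seq(2, 2 * n, 2), ] <- t(a2)
    rownames(haps) <- paste0(rep(colnames(gt), each = 2), c("_p", "_m"))
  }
  ref_depth <- alt_depth <- NULL
  if ("AD" %in% strsplit(v@gt[1, "FORMAT"], ":")[[1]]) {
    ad <- vcfR::extract.gt(v, element = "AD")
    ref_depth <- t(matrix(as.integer(sub(",.*", "", ad)), nrow = nrow(ad)))
    alt_depth <- t(matrix(as.integer(sub(".*,", "", ad)), nrow = nrow(ad)))
    rownames(ref_depth) <- rownames(alt_depth) <- colnames(gt)
  }
  list(positions = as.numeric(fix[, "POS"]),
       variants = fix[, "ID"],
       dosages = dos,
       haplotypes = haps,
       ref_depth = ref_depth, alt_depth = alt_depth)
}

#' Read/write pedigrees in PED/FAM dialect
#'
#' Six whitespace-separated columns: family, individual, father, mother,
#' sex, phenotype; `0` marks an unknown parent. The pedigree is validated
#' (duplicates, unknown parents, cycles) on read, order-independently.
#'
#' @param path file path.
#' @return [read_fam()]: a validated pedigree `data.frame` (`id`, `sire`,
#'   `dam`).
#' @export
read_fam <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("FAM file needs at least 4 columns")
  ped <- data.frame(id = as.character(tab[[2]]),
                    sire = ifelse(tab[[3]] == "0", NA_character_,
                                  as.character(tab[[3]])),
                    dam = ifelse(tab[[4]] == "0", NA_character_,
                                 as.character(tab[[4]])),
                    stringsAsFactors = FALSE)
  class(ped) <- c("cnv_pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' @rdname read_fam
#' @param ped pedigree `data.frame` to write.
#' @export
write_fam <- function(ped, path) {
  out <- data.frame(fid = "FAM1", id = ped$id,
                    father = ifelse(is.na(ped$sire), "0", ped$sire),
                    mother = ifelse(is.na(ped$dam), "0", ped$dam),
                    sex = 0L, pheno = -9L)
  atomic_write_table(out, path, col.names = FALSE)
}

#' Read a headered TSV table or feature-by-sample matrix
#'
#' Plain tab-separated tables (trait tables, count matrices) with a
#' header row. With `first_col_rownames = TRUE` the first column becomes
#' rownames and the rest a numeric matrix. Ragged rows are a parse
#' error.
#'
#' @param path TSV file.
#' @param first_col_rownames treat the first column as feature/sample ids.
#' @return a `data.frame`, or a numeric matrix when
#'   `first_col_rownames = TRUE`.
#' @export
read_tsv_matrix <- function(path, first_col_rownames = FALSE) {
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed TSV '", path, "': ",
                             conditionMessage(e)))
  if (!first_col_rownames) return(tab)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' Read/write BED regions with coordinate conversion
#'
#' BED is 0-based half-open; internal coordinates are 1-based inclusive.
#' The conversion happens exactly once, at this I/O boundary: a BED line
#' `6 88681766 88693545` becomes the internal interval
#' `[88681767, 88693545]`.
#'
#' @param path BED file.
#' @return [read_bed_regions()]: `data.frame` with `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @export
read_bed_regions <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = as.character(tab[[1]]),
             start = as.numeric(tab[[2]]) + 1,
             end = as.numeric(tab[[3]]),
             stringsAsFactors = FALSE)
}

#' @rdname read_bed_regions
#' @param regions `data.frame` with `chrom`, `start`, `end` (1-based
#'   inclusive) to export.
#' @export
write_bed_regions <- function(regions, path) {
  out <- data.frame(chrom = regions$chrom,
                    start = format(regions$start - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(regions$end, scientific = FALSE,
                                 trim = TRUE))
  atomic_write(do.call(paste, c(out, sep = "\t")), path)
}

#' Run the CNV-QTL analysis pipeline
#'
#' Chains the package stages in dependency order on a simulated cohort:
#' `simulate` (cohort + file exports), `genotype-cnv` (depth calling,
#' pedigree resolution, Mendelian check, tag SNPs), `assoc` (GRM, LMM
#' scan, conditional scan on the lead variant), `selscan` (iHS scan),
#' `eqtl` (normalization, outlier filter, residualization, cis scans for
#' every gene and the focal transcripts), `smr` (SMR/HEIDI per gene),
#' `coloc` (trait/eQTL p-value correlation), `report` (summary table).
#' Writes one TSV per product plus a JSON run manifest with the config
#' echo, thresholds, per-stage timings and output checksums.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @param stages character vector, subset of
#'   `c("simulate","genotype-cnv","assoc","selscan","eqtl","smr","coloc","report")`.
#' @param thresholds named list overriding analysis thresholds
#'   (`r2`, `maf`, `alpha`, `pcs`, `sd`, `window`, `smr_mlog10p`,
#'   `heidi_p`, `hidden_k`).
#' @return the manifest, invisibly (list, also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(cfg, out_dir,
                         stages = c("simulate", "genotype-cnv", "assoc",
                                    "selscan", "eqtl", "smr", "coloc",
                                    "report"),
                         thresholds = list()) {
  all_stages <- c("simulate", "genotype-cnv", "assoc", "selscan", "eqtl",
                  "smr", "coloc", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  thr <- utils::modifyList(list(r2 = 0.98, maf = 0.025, alpha = 0.01,
                                pcs = 4, sd = 3.5, window = 1e6,
                                smr_mlog10p = 5, heidi_p = 0.05,
                                hidden_k = 10), thresholds)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(cfg), seed = cfg$seed,
                   thresholds = thr, stages = stages, timings = list(),
                   outputs = list())
  env <- new.env()
  stamp <- function(stage, code) {
    t0 <- proc.time()[["elapsed"]]
    force(code)
    manifest$timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }
  need <- function(what, stage) {
    if (!exists(what, envir = env))
      stop("stage '", stage, "' requires output of an earlier stage ('",
           what, "' missing); run its producing stage first")
    get(what, envir = env)
  }

  if ("simulate" %in% stages) stamp("simulate", {
    coh <- simulate_cohort(cfg)
    assign("coh", coh, envir = env)
    write_vcf(coh$panel, file.path(out_dir, "cohort.vcf"),
              counts = coh$read_counts)
    write_fam(coh$pedigree, file.path(out_dir, "cohort.fam"))
    write_bed_regions(data.frame(chrom = "6", start = cfg$cnv_interval[1],
                                 end = cfg$cnv_interval[2]),
                      file.path(out_dir, "cnv.bed"))
    atomic_write_table(coh$trait, file.path(out_dir, "trait.tsv"))
    atomic_write_table(coh$depths, file.path(out_dir, "depths.tsv"))
    cnts <- data.frame(feature = rownames(coh$expression$gene_counts),
                       coh$expression$gene_counts, check.names = FALSE)
    atomic_write_table(cnts, file.path(out_dir, "gene_counts.tsv"))
    atomic_write(yaml::as.yaml(unclass(cfg)[setdiff(names(unclass(cfg)),
                                                    "cn_alleles")]),
                 file.path(out_dir, "config_echo.yaml"))
  })

  if ("genotype-cnv" %in% stages) stamp("genotype-cnv", {
    coh <- need("coh", "genotype-cnv")
    calls <- call_diploid_cn(coh$depths)
    res <- resolve_pedigree_cn(coh$pedigree, calls, A = cfg$cn_alleles)
    assign("cn", res, envir = env)
    atomic_write_table(cbind(calls["fold_change"], res$genotypes),
                       file.path(out_dir, "cn_genotypes.tsv"))
    atomic_write_table(res$mendel$trios, file.path(out_dir, "mendel.tsv"))
    tags <- find_tag_snps(panel_dosages(coh$panel),
                          mul_dosage(coh$cn_pairs),
                          coh$panel$positions, cfg$cnv_interval,
                          r2_threshold = thr$r2)
    assign("tags", tags, envir = env)
    atomic_write_table(tags, file.path(out_dir, "tag_snps.tsv"))
  })

  if ("assoc" %in% stages) stamp("assoc", {
    coh <- need("coh", "assoc")
    D <- panel_dosages(coh$panel)
    keep <- maf_filter(colMeans(D) / 2, thr$maf)
    grm <- compute_grm(D, coh$panel$positions,
                       exclude = cfg$cnv_interval + c(-1e6, 1e6))
    fit <- fit_null_lmm(coh$trait$y, grm)
    scan <- mixed_model_scan(fit, D[, keep, drop = FALSE],
                             positions = coh$panel$positions[keep])
    assign("assoc", scan, envir = env)
    assign("lmm", fit, envir = env)
    atomic_write_table(scan, file.path(out_dir, "assoc_trait.tsv"))
    lead <- scan$variant[which.max(scan$mlog10p)]
    cond <- mixed_model_scan(fit, D[, keep, drop = FALSE],
                             positions = coh$panel$positions[keep],
                             conditional = lead)
    atomic_write_table(cond, file.path(out_dir, "assoc_trait_conditional.tsv"))
    manifest$outputs$bonferroni <- bonferroni_threshold(sum(keep),
                                                        thr$alpha)
    manifest$outputs$lead_variant <- lead
  })

  if ("selscan" %in% stages) stamp("selscan", {
    coh <- need("coh", "selscan")
    scan <- standardize_ihs(ihs_scan(coh$panel))
    assign("ihs", scan, envir = env)
    atomic_write_table(scan, file.path(out_dir, "ihs.tsv"))
  })

  if ("eqtl" %in% stages) stamp("eqtl", {
    coh <- need("coh", "eqtl")
    norm <- normalize_counts(coh$expression$gene_counts)
    filt <- pc_outlier_filter(norm$normalized, n_pcs = thr$pcs,
                              sd_cutoff = thr$sd)
    kept <- filt$retained
    feats <- coh$expression$features
    cis_genes <- feats$feature[feats$chrom == "6"]
    resid <- residualize_hidden_factors(
      norm$normalized[, kept, drop = FALSE],
      K = min(thr$hidden_k, length(kept) - 2L),
      exclude_features = cis_genes)
    D <- panel_dosages(coh$panel)[kept, , drop = FALSE]
    cis_idx <- which(feats$chrom == "6")
    scans <- lapply(cis_idx, function(i) {
      cis_eqtl_scan(resid$residualized[feats$feature[i], ],
                    D, coh$panel$positions,
                    feature_pos = (feats$start[i] + feats$end[i]) / 2,
                    window = thr$window)
    })
    names(scans) <- feats$feature[cis_idx]
    assign("eqtl", scans, envir = env)
    assign("eqtl_samples", kept, envir = env)
    atomic_write_table(scans$GC, file.path(out_dir, "eqtl_GC.tsv"))
  })

  if ("smr" %in% stages) stamp("smr", {
    coh <- need("coh", "smr")
    scans <- need("eqtl", "smr")
    gwas <- need("assoc", "smr")
    kept <- need("eqtl_samples", "smr")
    D <- panel_dosages(coh$panel)[kept, , drop = FALSE]
    smr <- do.call(rbind, lapply(names(scans), function(g) {
      eq <- scans[[g]]
      shared <- intersect(gwas$variant, eq$variant)
      if (length(shared) < 3)
        return(NULL)
      ld <- suppressWarnings(stats::cor(D[, shared, drop = FALSE]))
      ld[!is.finite(ld)] <- 0
      smr_heidi(gwas, eq, ld, gene = g,
                smr_mlog10p = thr$smr_mlog10p, heidi_p = thr$heidi_p)
    }))
    assign("smr", smr, envir = env)
    atomic_write_table(smr, file.path(out_dir, "smr.tsv"))
  })

  if ("coloc" %in% stages) stamp("coloc", {
    gwas <- need("assoc", "coloc")
    scans <- need("eqtl", "coloc")
    cl <- coloc_correlation(gwas, scans$GC)
    assign("coloc", cl, envir = env)
    atomic_write_table(cl$data, file.path(out_dir, "coloc_GC.tsv"))
    manifest$outputs$rho_GC <- cl$rho
  })

  if ("report" %in% stages) stamp("report", {
    lines <- c("cnvqtl pipeline report", "======================")
    if (exists("cn", envir = env)) {
      cn <- get("cn", envir = env)
      lines <- c(lines, sprintf(
        "CN genotyping: %d/%d resolved; Mendelian incompatibilities: %d",
        sum(cn$genotypes$resolved), nrow(cn$genotypes),
        cn$mendel$n_incompatible))
    }
    if (exists("tags", envir = env))
      lines <- c(lines, sprintf("Tag SNPs at r2 >= %.2f in CNV: %d",
                                thr$r2,
                                sum(get("tags", envir = env)$in_cnv)))
    if (exists("assoc", envir = env)) {
      a <- get("assoc", envir = env)
      lines <- c(lines, sprintf(
        "Association lead: %s at -log10p = %.2f (threshold %.2f)",
        a$variant[which.max(a$mlog10p)], max(a$mlog10p, na.rm = TRUE),
        manifest$outputs$bonferroni))
    }
    if (exists("ihs", envir = env)) {
      s <- get("ihs", envir = env)
      top <- s[which.max(abs(s$ihs_std)), ]
      lines <- c(lines, sprintf("iHS peak |std| = %.2f at %s",
                                abs(top$ihs_std),
                                format(top$position, big.mark = ",")))
    }
    if (exists("smr", envir = env)) {
      sm <- get("smr", envir = env)
      pri <- sm$gene[sm$prioritized]
      lines <- c(lines, sprintf("SMR prioritized gene(s): %s",
                                if (length(pri)) paste(pri, collapse = ", ")
                                else "none"))
    }
    if (exists("coloc", envir = env))
      lines <- c(lines, sprintf("Trait/GC-eQTL p-value correlation rho = %.2f",
                                get("coloc", envir = env)$rho))
    atomic_write(lines, file.path(out_dir, "report.txt"))
  })

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  tmp <- tempfile(tmpdir = out_dir, fileext = ".tmp")
  writeLines(json, tmp)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
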