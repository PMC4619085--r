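## cli_config: the end-to-end design workflow behind the command-line
## wrapper (inst/scripts/crisprdel-design.R).

.configHash <- function(cfg, tpl) {
  txt <- paste(c(cfg@windowBp, cfg@maxPairs, cfg@requireGForU6,
                 cfg@allowPrependG, cfg@minPairScore, cfg@maxMismatch,
                 tpl@gibson5, tpl@scaffoldFrag, tpl@bsmbiCassette,
                 tpl@h1Frag, tpl@gibson3, tpl@t2Orientation),
               collapse = "|")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

.provenanceHeader <- function(seed, hash) {
  c(paste0("# crisprDel ", as.character(packageVersion("crisprDel"))),
    paste0("# seed=", seed, " config=", hash))
}

.writeTsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Run the full deletion-design workflow on a batch of targets
#'
#' For each target region: designs ranked guide pairs, assembles the Insert-1
#' oligo of the best pair, validates it through the simulated two-step
#' cloning, picks diagnostic primers and predicts the genotyping plan.
#' Writes a design report TSV, an oligo FASTA (one 165-mer per successful
#' target), BED files of deletion intervals and cut sites, and a genotyping
#' plan TSV, all carrying a provenance header (tool version, config hash,
#' seed). Per-target failures are collected, not fatal to the batch.
#'
#' @param genome FASTA path or named [Biostrings::DNAStringSet].
#' @param targets BED path or [GenomicRanges::GRanges] with a `name` column.
#' @param outDir Output directory (created if needed).
#' @param cfg A [designConfig()].
#' @param template Template file path or [InsertTemplate-class]; default the
#'   shipped template.
#' @param seed Integer seed recorded in every output header (the design
#'   itself is deterministic; the seed feeds any downstream simulation).
#' @param toleranceBp Optional fixed band tolerance for the genotyping plans.
#' @return Invisibly, a list with `results` (per-target list: pairs, oligo,
#'   plan, primers), `failures` (named character of error messages) and
#'   `files` (paths written). `length(failures) > 0` signals partial failure.
#' @export
runDesign <- function(genome, targets, outDir, cfg = designConfig(),
                      template = NULL, seed = 1L, toleranceBp = NULL) {
  if (is.character(genome)) genome <- readGenome(genome)
  genome <- .asGenomeSet(genome)
  if (is.character(targets)) targets <- readTargetsBed(targets)
  if (is.null(mcols(targets)$name))
    mcols(targets)$name <- paste0("target_", seq_along(targets))
  tpl <- if (is.null(template)) defaultInsertTemplate()
         else if (is.character(template)) readInsertTemplate(template)
         else template
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- .configHash(cfg, tpl)
  hdr <- .provenanceHeader(seed, hash)

  results <- list()
  failures <- character(0)
  for (i in seq_along(targets)) {
    nm <- mcols(targets)$name[i]
    res <- tryCatch({
      pairs <- designPairs(genome, targets[i], cfg)
      best <- pairs[[1]]
      oligo <- assembleInsert1(protospacer(u6Guide(best)),
                               protospacer(h1Guide(best)), tpl)
      simulateCloning(best, tpl)   # hard validation of the construct
      chrom <- as.character(seqnames(targets[i]))
      primers <- tryCatch(pickPrimers(genome[chrom], best),
                          error = function(e) NULL)
      plan <- if (!is.null(primers))
        predictAmplicons(genome[chrom], best, primers, name = nm,
                         nominalLen = width(targets[i]),
                         toleranceBp = toleranceBp)
      else NULL
      list(name = nm, pairs = pairs, best = best, oligo = oligo,
           primers = primers, plan = plan)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[nm] <- conditionMessage(res)
      message("design failed for ", nm, ": ", conditionMessage(res))
    } else {
      results[[nm]] <- res
    }
  }

  files <- character(0)
  if (length(results)) {
    report <- do.call(rbind, lapply(results, function(r)
      pairTable(r$pairs, r$name)))
    files["report"] <- .writeTsv(report, file.path(outDir, "design_report.tsv"),
                                 hdr)
    oligos <- lapply(results, `[[`, "oligo")
    names(oligos) <- names(results)
    files["oligos_fasta"] <- file.path(outDir, "oligos.fa")
    writeOligoPool(oligos, fastaPath = files[["oligos_fasta"]],
                   tsvPath = file.path(outDir, "oligo_order_sheet.tsv"))
    files["order_sheet"] <- file.path(outDir, "oligo_order_sheet.tsv")
    dels <- do.call(c, unname(lapply(results, function(r) {
      g <- deletionRegion(r$best)
      mcols(g)$name <- r$name
      g
    })))
    files["deletions_bed"] <- writeBed(dels, file.path(outDir,
                                                       "deletions.bed"))
    cutsGr <- do.call(c, unname(lapply(results, function(r) {
      cuts <- cutSite(r$best)
      g <- GRanges(seqnames(deletionRegion(r$best))[1],
                   IRanges(cuts + 1L, width = 1L))
      mcols(g)$name <- paste0(r$name, "_cut", seq_along(cuts))
      g
    })))
    files["cuts_bed"] <- writeBed(cutsGr, file.path(outDir, "cut_sites.bed"))
    plans <- Filter(Negate(is.null), lapply(results, `[[`, "plan"))
    if (length(plans)) {
      planDf <- do.call(rbind, lapply(plans, planTable))
      files["plans"] <- .writeTsv(planDf,
                                  file.path(outDir, "genotyping_plans.tsv"),
                                  hdr)
    }
  }
  out <- list(results = results, failures = failures, files = files,
              seed = seed, configHash = hash)
  invisible(out)
}
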