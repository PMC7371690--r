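# Pipeline orchestration: run every applicable stage on a genome + gene
# table (+ optional grouped alignment) and write a machine-readable report
# bundle. With fixed seeds the bundle is byte-identical across runs.

#' Run the full characterization pipeline and write a report bundle
#'
#' Stages run depend on the inputs: a gene table alone yields the structural
#' summary; adding a genome sequence yields composition, RSCU and
#' control-region motif reports; adding a grouped alignment yields the
#' distance/divergence/AMOVA comparison and a bootstrapped
#' neighbor-joining tree.
#'
#' Outputs written to `out_dir`: `summary.json`, and as applicable
#' `composition.tsv`, `rscu.tsv`, `motifs.json`, `compare.json`,
#' `tree.nwk`, plus a `manifest.json` recording the package version, the
#' seed, and an md5 checksum of every file written.
#'
#' @param gene_table Gene table (required).
#' @param genome Optional [mito_genome()] matching the gene table.
#' @param aln Optional alignment tibble with a `group` column.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed for the stochastic stages (AMOVA permutations,
#'   bootstrap).
#' @param n_permutations AMOVA permutations.
#' @param n_bootstrap Bootstrap replicates.
#'
#' @return Invisibly, a named character vector of the files written.
#' @export
full_report <- function(gene_table, genome = NULL, aln = NULL,
                        out_dir = ".", seed = 1L, n_permutations = 1000L,
                        n_bootstrap = 100L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  emit_json <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written[[name]] <<- path
  }
  summ <- structural_summary(gene_table)
  emit_json(as.list(glance(summ)), "summary.json")

  if (!is.null(genome)) {
    comp <- class_profiles(genome, gene_table, per_gene = TRUE)
    path <- file.path(out_dir, "composition.tsv")
    readr::write_tsv(comp, path, progress = FALSE)
    written[["composition.tsv"]] <- path

    counts <- extract_codons(genome, gene_table)
    path <- file.path(out_dir, "rscu.tsv")
    readr::write_tsv(rscu(counts), path, progress = FALSE)
    written[["rscu.tsv"]] <- path

    cr <- control_region_report(genome, gene_table)
    emit_json(list(
      motifs = lapply(seq_len(nrow(cr$motifs)), function(i) {
        list(motif = cr$motifs$motif[i], count = cr$motifs$count[i],
             positions = cr$motifs$positions[[i]])
      }),
      terminal_polyc = cr$terminal_polyc
    ), "motifs.json")
  }

  if (!is.null(aln)) {
    if (!"group" %in% names(aln)) {
      abort("alignment must carry a 'group' column for the comparative stage",
            class = "mito_error_grouping")
    }
    dm <- dist_matrix(aln, "p_distance")
    am <- amova(aln, n_permutations = n_permutations, seed = seed)
    labs <- unique(aln$group)
    pairs <- utils::combn(labs, 2, simplify = FALSE)
    div <- purrr::map_dfr(pairs, function(pr) {
      sub <- filter(aln, .data$group %in% pr)
      tibble(group1 = pr[1], group2 = pr[2],
             p_distance = group_divergence(sub, model = "p_distance"))
    })
    emit_json(list(
      distances = tidy(dm),
      divergence = div,
      amova = as.list(glance(am))
    ), "compare.json")
    if (nrow(aln) >= 3L) {
      bt <- bootstrap_tree(aln, "nj", n_replicates = n_bootstrap, seed = seed)
      path <- file.path(out_dir, "tree.nwk")
      writeLines(write_newick(bt$tree), path)
      written[["tree.nwk"]] <- path
    }
  }

  manifest <- list(
    package = "mitocompare",
    version = as.character(utils::packageVersion("mitocompare")),
    seed = seed,
    files = lapply(written, function(p) unname(tools::md5sum(p)))
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  written[["manifest.json"]] <- path
  invisible(written)
}
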