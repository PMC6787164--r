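#' Annotate a ranked gene list with pathway membership
#'
#' Keeps the genes of a ranked differential list that belong to at least one
#' pathway gene set, preserving the input order, and records each gene's
#' full pathway membership. This is the first step of the signature-building
#' cascade (ranked hits -> pathway-involved -> enzymatic -> role-filtered).
#'
#' @param ranked_genes Character vector of gene ids, best first.
#' @param pathways Gene-set tibble (`set_name`, `gene_id`, optional
#'   `category`), e.g. from [read_gmt()].
#' @return Tibble with `gene_id`, `pathways` (list-column of set names) and
#'   `n_pathways`, in the input ranking order.
#' @export
intersect_with_pathways <- function(ranked_genes, pathways) {
  check_gene_sets(pathways)
  if (length(ranked_genes) == 0L) {
    abort("`ranked_genes` is empty.")
  }
  membership <- pathways |>
    dplyr::filter(.data$gene_id %in% ranked_genes) |>
    dplyr::distinct(.data$gene_id, .data$set_name) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(pathways = list(sort(.data$set_name)), .groups = "drop")
  out <- tibble::tibble(gene_id = ranked_genes) |>
    dplyr::inner_join(membership, by = "gene_id") |>
    dplyr::mutate(n_pathways = purrr::map_int(.data$pathways, length))
  out
}

valid_roles <- c("catabolic", "anabolic", "enzymatic", "non-enzymatic")

#' Filter pathway-annotated candidates by enzyme role into a signature
#'
#' Keeps the candidates whose annotated enzyme role matches `role`. The role
#' `"enzymatic"` matches both catabolic and anabolic annotations. Genes
#' annotated `"unknown"` (or absent from the annotation table) never match:
#' a signature only admits genes whose function could be established.
#'
#' @param candidates Annotated gene tibble from [intersect_with_pathways()]
#'   (any tibble with `gene_id`, optionally `pathways`, works).
#' @param annotation Tibble mapping `gene_id` to `role` (one of catabolic,
#'   anabolic, non-enzymatic, unknown).
#' @param role Role to keep: "catabolic", "anabolic", "enzymatic" or
#'   "non-enzymatic".
#' @param name Signature name.
#' @return A `gene_signature` object; its `genes` tibble carries per-gene
#'   provenance (source pathways, role, survival flag placeholder).
#' @export
build_signature <- function(candidates, annotation, role, name) {
  role <- match.arg(role, valid_roles)
  if (!is.data.frame(annotation) ||
      !all(c("gene_id", "role") %in% names(annotation))) {
    abort("`annotation` must have `gene_id` and `role` columns.")
  }
  if (anyDuplicated(annotation$gene_id)) {
    abort("`annotation` must assign exactly one role per gene.")
  }
  if (!"gene_id" %in% names(candidates)) {
    abort("`candidates` must have a `gene_id` column.")
  }
  gene_role <- annotation$role[match(candidates$gene_id, annotation$gene_id)]
  keep <- if (role == "enzymatic") {
    gene_role %in% c("catabolic", "anabolic")
  } else {
    !is.na(gene_role) & gene_role == role
  }
  genes <- candidates[keep, , drop = FALSE]
  genes$role <- gene_role[keep]
  if (!"pathways" %in% names(genes)) {
    genes$pathways <- replicate(nrow(genes), character(), simplify = FALSE)
  }
  genes$survival_associated <- NA
  if (nrow(genes) == 0L) {
    warn(sprintf("Signature `%s` is empty: no candidate matched role `%s`.",
                 name, role))
  }
  new_signature(name, genes[c("gene_id", "pathways", "role", "survival_associated")],
                source = sprintf("role-filter:%s", role))
}

new_signature <- function(name, genes, source = "derived") {
  structure(
    list(name = name, genes = tibble::as_tibble(genes), source = source),
    class = "gene_signature"
  )
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d gene(s) [%s]\n",
              x$name, nrow(x$genes), x$source))
  if (nrow(x$genes) > 0L) {
    cat(" ", paste(head(x$genes$gene_id, 8L), collapse = ", "))
    if (nrow(x$genes) > 8L) cat(", ...")
    cat("\n")
  }
  invisible(x)
}

#' @rdname build_signature
#' @param x A `gene_signature`.
#' @param ... Unused.
#' @export
tidy.gene_signature <- function(x, ...) {
  dplyr::mutate(x$genes, signature = x$name, .before = 1L)
}

#' Gene ids of a signature
#' @param signature A `gene_signature`.
#' @return Character vector of member gene ids.
#' @export
signature_genes <- function(signature) {
  if (!inherits(signature, "gene_signature")) {
    abort("`signature` must be a gene_signature.")
  }
  signature$genes$gene_id
}

#' Split a parent signature into per-process sub-signatures
#'
#' Builds one child signature per pathway category (or per set when no
#' `category` column is present), each holding the parent genes that belong
#' to that category's sets. A gene belonging to several processes appears in
#' several children; the union of children is contained in the parent.
#' Categories disjoint from the parent yield an empty child with a warning.
#'
#' @param parent A non-empty `gene_signature`.
#' @param pathways Gene-set tibble with `set_name`, `gene_id` and optionally
#'   `category`.
#' @return Named list of `gene_signature` children.
#' @export
derive_sub_signatures <- function(parent, pathways) {
  if (!inherits(parent, "gene_signature") || nrow(parent$genes) == 0L) {
    abort("`parent` must be a non-empty gene_signature.")
  }
  check_gene_sets(pathways)
  key <- if ("category" %in% names(pathways)) "category" else "set_name"
  groups <- split(pathways$gene_id, pathways[[key]])
  purrr::imap(groups, function(members, label) {
    genes <- parent$genes[parent$genes$gene_id %in% members, , drop = FALSE]
    if (nrow(genes) == 0L) {
      warn(sprintf("Sub-signature `%s` of `%s` is empty.", label, parent$name))
    }
    new_signature(paste(parent$name, label, sep = ":"), genes,
                  source = sprintf("subset:%s", label))
  })
}

#' Select survival-associated genes shared by multiple processes
#'
#' From a list of per-process sub-signatures, keeps the genes that are (a)
#' flagged survival-associated and (b) members of at least `min_processes`
#' children, ordered by membership count descending then gene id. This is
#' the multi-process hit selection used to nominate key functional targets.
#'
#' @param children List of `gene_signature` objects (e.g. from
#'   [derive_sub_signatures()]).
#' @param min_processes Minimum number of children a gene must appear in.
#' @param survival_flags Named logical vector (or tibble with `gene_id`,
#'   `flagged`) marking survival-associated genes; genes without an entry
#'   count as not associated.
#' @return Tibble with `gene_id` and `n_processes`, sorted as described.
#' @export
select_multiprocess_genes <- function(children, min_processes = 3,
                                      survival_flags) {
  if (min_processes < 1) abort("`min_processes` must be >= 1.")
  if (is.data.frame(survival_flags)) {
    if (!all(c("gene_id", "flagged") %in% names(survival_flags))) {
      abort("`survival_flags` data frame needs `gene_id` and `flagged` columns.")
    }
    survival_flags <- setNames(survival_flags$flagged, survival_flags$gene_id)
  }
  counts <- children |>
    purrr::map(signature_genes) |>
    purrr::map(unique) |>
    unlist(use.names = FALSE) |>
    table()
  if (length(counts) == 0L) {
    return(tibble::tibble(gene_id = character(), n_processes = integer()))
  }
  out <- tibble::tibble(
    gene_id = names(counts),
    n_processes = as.integer(counts)
  )
  flagged <- isTRUE_vec(survival_flags[out$gene_id])
  out <- out[flagged & out$n_processes >= min_processes, , drop = FALSE]
  dplyr::arrange(out, dplyr::desc(.data$n_processes), .data$gene_id)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Build a literal (fixed) signature from a gene list
#'
#' For signatures whose membership is given directly rather than derived
#' from a filter cascade — e.g. a two-gene alcohol-metabolism signature
#' {ADH1A, ALDH2}. Duplicates are collapsed with a warning; an empty list is
#' an error. Provenance is marked "fixed".
#'
#' @param name Signature name.
#' @param gene_ids Non-empty character vector of member genes.
#' @return A `gene_signature`.
#' @export
#' @examples
#' fixed_signature("Alco_Met-GS", c("ADH1A", "ALDH2"))
fixed_signature <- function(name, gene_ids) {
  if (length(gene_ids) == 0L) abort("A fixed signature needs at least one gene.")
  if (anyDuplicated(gene_ids)) {
    warn(sprintf("Duplicate gene id(s) collapsed in fixed signature `%s`.", name))
    gene_ids <- unique(gene_ids)
  }
  genes <- tibble::tibble(
    gene_id = gene_ids,
    pathways = replicate(length(gene_ids), "fixed", simplify = FALSE),
    role = NA_character_,
    survival_associated = NA
  )
  new_signature(name, genes, source = "fixed")
}

#' Example fixture for the signature-discovery cascade
#'
#' Constructs, in code, a self-contained fixture shaped like a real
#' discovery run: a ranked list of 1,000 downregulated genes of which 159
#' belong to metabolic pathway sets, an enzyme-role annotation under which
#' 119 of those are enzymes — 110 catabolic and 9 anabolic — and five
#' overlapping process sets within the catabolic module. Useful for
#' demonstrating and testing the filter cascade without external pathway
#' databases.
#'
#' @param seed Integer seed controlling the (arbitrary) placement of genes.
#' @return List with `ranked_genes` (1,000 ids), `pathways` (gene-set
#'   tibble, category "metabolic-pathway"), `annotation` (gene_id/role
#'   tibble covering all 1,000 genes).
#' @export
example_cascade <- function(seed = 42L) {
  set.seed(seed)
  ranked <- sprintf("dn%04d", seq_len(1000))
  in_pathway <- sort(sample(ranked, 159))
  catabolic <- in_pathway[1:110]
  anabolic <- in_pathway[111:119]
  nonenz <- in_pathway[120:159]
  processes <- c("aa_met", "lipid_met", "carb_met", "drug_met", "retinol_met")
  k <- sample(1:5, length(in_pathway), replace = TRUE,
              prob = c(0.45, 0.3, 0.15, 0.07, 0.03))
  pathways <- purrr::map2(in_pathway, k, function(g, kk) {
    tibble::tibble(set_name = sample(processes, kk),
                   category = "metabolic-pathway", gene_id = g)
  }) |> dplyr::bind_rows() |> dplyr::arrange(.data$set_name, .data$gene_id)
  annotation <- tibble::tibble(
    gene_id = ranked,
    role = dplyr::case_when(
      ranked %in% catabolic ~ "catabolic",
      ranked %in% anabolic ~ "anabolic",
      ranked %in% nonenz ~ "non-enzymatic",
      TRUE ~ sample(c("non-enzymatic", "unknown"), 1000, replace = TRUE)[seq_along(ranked)]
    )
  )
  list(ranked_genes = ranked, pathways = pathways, annotation = annotation)
}
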