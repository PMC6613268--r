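# Plain-text dataset interchange. Genotype and breed-of-origin (BOA) files
# are tab-separated with an animal_id column followed by one column per
# marker, in the order of the marker-info sidecar; pedigree and phenotype
# files are CSV.

#' Write a simulated dataset to disk
#'
#' Emits five files: `genotypes.tsv` (counted-allele dosages 0/1/2 for all
#' genotyped animals), `boa.tsv` (for CB animals only: counted-allele dosage
#' of the sire-line-origin gamete, 0/1, with 9 reserved for unassigned),
#' `markers.tsv` (marker id, chromosome, position in Morgans, counted
#' allele), `pedigree.csv` and `phenotypes.csv`.
#'
#' @param pop A `cbp_pop` object (phenotypes included).
#' @param dir Output directory, created if missing.
#' @return Invisibly, the named vector of file paths.
#' @export
write_dataset <- function(pop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             boa = file.path(dir, "boa.tsv"),
             markers = file.path(dir, "markers.tsv"),
             pedigree = file.path(dir, "pedigree.csv"),
             phenotypes = file.path(dir, "phenotypes.csv"))
  ped <- pop$pedigree
  geno <- genotypes(pop)
  gdt <- data.table::data.table(animal_id = rownames(geno))
  if (nrow(geno)) gdt <- cbind(gdt, data.table::as.data.table(geno))
  data.table::fwrite(gdt, paths["genotypes"], sep = "\t")
  cb <- ped$id[ped$genetic_group == "CB"]
  boa <- boa_sire_dosage(pop, cb)
  bdt <- data.table::data.table(animal_id = cb)
  if (length(cb)) bdt <- cbind(bdt, data.table::as.data.table(boa))
  data.table::fwrite(bdt, paths["boa"], sep = "\t")
  data.table::fwrite(pop$map, paths["markers"], sep = "\t")
  data.table::fwrite(ped, paths["pedigree"])
  phen <- pop$phenotypes
  if (is.null(phen)) phen <- data.frame(animal_id = character(), trait = character(),
                                        value = numeric(), batch = integer(),
                                        pen = integer(), sex = character(),
                                        age = integer(), day = character(),
                                        dam_id = character(),
                                        genetic_group = character())
  data.table::fwrite(phen, paths["phenotypes"])
  invisible(paths)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing the five dataset files.
#' @return A list of class `cbp_dataset` with elements `geno` (integer
#'   matrix, animals x markers), `boa` (integer matrix, CB animals x
#'   markers), `map`, `pedigree` and `phenotypes` (data frames).
#' @export
read_dataset <- function(dir) {
  need <- c("genotypes.tsv", "boa.tsv", "markers.tsv", "pedigree.csv",
            "phenotypes.csv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss)) stop("missing dataset files: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  to_mat <- function(path) {
    dt <- data.table::fread(path, sep = "\t")
    ids <- dt$animal_id
    m <- as.matrix(dt[, -1, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- ids
    m
  }
  map <- as.data.frame(data.table::fread(file.path(dir, "markers.tsv")))
  geno <- to_mat(file.path(dir, "genotypes.tsv"))
  boa <- to_mat(file.path(dir, "boa.tsv"))
  structure(list(geno = geno, boa = boa, map = map,
                 pedigree = as.data.frame(data.table::fread(
                   file.path(dir, "pedigree.csv"),
                   na.strings = c("NA", ""))),
                 phenotypes = as.data.frame(data.table::fread(
                   file.path(dir, "phenotypes.csv")))),
            class = "cbp_dataset")
}

#' Bundle an in-memory population as an analysis dataset
#'
#' Convenience equivalent of [write_dataset()] + [read_dataset()] without
#' touching disk; downstream QC and scenario functions consume this form.
#'
#' @param pop A `cbp_pop` object with phenotypes.
#' @return A `cbp_dataset` list (see [read_dataset()]).
#' @export
as_dataset <- function(pop) {
  ped <- pop$pedigree
  cb <- ped$id[ped$genetic_group == "CB"]
  structure(list(geno = genotypes(pop), boa = boa_sire_dosage(pop, cb),
                 map = pop$map, pedigree = ped, phenotypes = pop$phenotypes),
            class = "cbp_dataset")
}
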