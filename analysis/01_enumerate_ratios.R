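#!/usr/bin/env Rscript
# Exact Mendelian expectations for every cross used by the three procedures,
# from the enumeration oracle. Writes results/enumeration/ratios.csv.
#
# Expected output: the classic ratios -- 3/16 double positives in the
# dihybrid F2, 100% Dpy / 75% Green at the cross's F3 stage, 100% vs 75% Red
# among nonGreen F2 in the balancer linkage test, and 0% vs 50% Red F2 males
# in the X test.

suppressMessages(library(wormbench))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
set.seed(seed)

reg <- default_registry()
ctl <- wb_control(spontaneous_male_rate = 0)
outdir <- file.path("results", "enumeration")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

rows <- list()
note <- function(cross, quantity, value) {
  rows[[length(rows) + 1L]] <<- data.frame(cross = cross, quantity = quantity,
                                           value = value)
  cat(sprintf("%-38s %-34s %.4f\n", cross, quantity, value))
}

f1 <- make_genotype(reg, heterozygous = c("vsIs28", "e61"))
d <- enumerate_offspring(f1, registry = reg, control = ctl)
note("dihybrid F1 self (vsIs28/+; e61/+)", "P(Green & Dpy)",
     phenotype_fraction(d, tags_all = c("Green", "Dpy")))
note("dihybrid F1 self (vsIs28/+; e61/+)", "phenotype classes",
     nrow(phenotype_classes(d)))

f3 <- make_genotype(reg, homozygous = "e61", heterozygous = "vsIs28")
d <- enumerate_offspring(f3, registry = reg, control = ctl)
note("F3 self (e61/e61; vsIs28/+)", "P(Dpy)", phenotype_fraction(d, tags_all = "Dpy"))
note("F3 self (e61/e61; vsIs28/+)", "P(Green)",
     phenotype_fraction(d, tags_all = "Green"))

linked <- make_genotype(reg, heterozygous = "vsIs33", balancers = "nT1")
d <- enumerate_offspring(linked, registry = reg, control = ctl)
note("linkage F1 self, transgene linked", "P(Red | nonGreen)",
     phenotype_fraction(d, tags_all = "Red", among = list(tags_none = "Green")))

unlinked <- make_genotype(reg, heterozygous = "vsIs33", balancers = "mIn1")
d <- enumerate_offspring(unlinked, registry = reg, control = ctl)
note("linkage F1 self, transgene unlinked", "P(Red | nonGreen)",
     phenotype_fraction(d, tags_all = "Red", among = list(tags_none = "Green")))

f1m <- make_genotype(reg, heterozygous = "vsIs33", sex = "male")
d <- enumerate_offspring(make_genotype(reg), f1m, reg, ctl)
note("X test, autosomal transgene", "P(Red | male)",
     phenotype_fraction(d, tags_all = "Red", among = list(sex = "male")))

scx <- make_mapping_scenario("X")
f1mx <- make_genotype(scx$registry, heterozygous = scx$transgene, sex = "male")
d <- enumerate_offspring(make_genotype(scx$registry), f1mx, scx$registry, ctl)
note("X test, X-linked transgene", "P(Red | male)",
     phenotype_fraction(d, tags_all = "Red", among = list(sex = "male")))

tab <- do.call(rbind, rows)
utils::write.csv(tab, file.path(outdir, "ratios.csv"), row.names = FALSE)
write_manifest(wb_config(seed = seed, control = ctl, outdir = outdir), outdir,
               extra = list(driver = "01_enumerate_ratios"))
cat("wrote", file.path(outdir, "ratios.csv"), "\n")
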