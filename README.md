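# lantivar

Tools for the in-silico characterization of nisin-like lanthipeptide
variants and their biosynthetic gene clusters.

Lantibiotics such as nisin are ribosomally synthesized peptides in
which Ser/Thr residues are enzymatically dehydrated (to Dha/Dhb) and
cross-linked to Cys as lanthionine rings. New natural variants are
described by a small, standard set of desk analyses, and `lantivar`
packages exactly those:

* **Variant reconstruction and naming** — apply or derive
  reference-numbered edit lists (`Ile4Lys`, `ΔSer29`, `insAsn32`)
  between mature core peptides, from deterministic global alignments
  (BLOSUM62, affine gaps, documented tie-break). Percent identity is
  `100 × identities / residue-residue columns`.
* **Mass model** — unmodified peptide mass (residue sum + water) and
  dehydration-aware modified masses (`−n × 18.0153` Da); infer the
  dehydration count from an observed mass.
* **Identity matrices and dendrograms** — all-pairs percent identity,
  neighbour-joining (distance `100 − identity`, deterministic
  tie-break, clamped branch lengths) or UPGMA, written as Newick.
* **Cluster architecture** — layout strings over the canonical role
  alphabet `A B T C I P R K F E G`, adjacency/breakpoint comparison of
  layouts, and role-set classification (`full_production`,
  `immunity_sensing_subset` = exactly `RKFEG`, `partial`, `none`).
* **Regulatory elements** — consensus scanning for nisin-cluster
  promoter boxes with fixed spacers, `TCT-N8-TCT` direct repeats, and
  Rho-independent terminators under a nearest-neighbour hairpin energy
  model with −5 / −10 kcal/mol reporting and strength thresholds.
* **Pangenome screen** — bacterial ORF calling (table 11, both
  strands), homolog assignment by global protein identity (≥90%
  default), per-genome classification and summary tables.
* **Synthetic data** — seeded generators for mutated peptides, planted
  regulatory sequences, whole operon contigs, and multi-genome
  pangenomes, each with a truth manifest.

## Worked example

```r
library(lantivar)

refs <- nisin_reference_peptides()   # nisA, nisZ, nisE, nisU cores
characterize_variants(refs$nisA, refs$nisE, observed_masses = 3100.8)
```

```
  query_id ref_id n_edits
1     nisE   nisA      10
                                                                            edit_names
1 Ile4Lys,Gly18Thr,Asn20Pro,Met21Ile,His27Gly,ΔSer29,ΔIle30,Val32Phe,Ser33Gly,Lys34Asn
  percent_identity hinge unmodified_mass observed_mass n_dehydrations
1               75   PIK          3245.9        3100.8              8
  dehydrated_mass
1          3101.7
```

Read: the mature nisin E core differs from nisin A by ten edits (eight
substitutions and two deletions, named in nisin A numbering), is 75.0%
identical to it, carries the PIK hinge at positions 20–22, weighs
3245.9 Da unmodified, and the observed 3100.8 Da is explained by eight
dehydrations (predicted 3101.7 Da, residual < 1 Da).

Cluster and genome level:

```r
im <- identity_matrix(refs)
nj_tree(im)
#> ((nisA:1.47059,nisZ:1.47059):22.3197,nisE:1.20968,nisU:5.24194);

compare_layouts("ABTCIPRKFEG", "PRKAFEGBTCI")
#> $shared_adjacencies [1] 7   $breakpoints [1] 3

pg  <- make_pangenome(n_genomes = 44, n_full = 6, n_subset = 20,
                      mutation_rate = 0.02, seed = 1)
res <- screen_pangenome(pg$genomes)
res$summary
#>                  category count  fraction
#> 1         full_production     6 0.1363636
#> 2 immunity_sensing_subset    20 0.4545455
#> 3                 partial     0 0.0000000
#> 4                    none    18 0.4090909
```

A thin command-line front-end (`exec/lantivar`) exposes the same
stages as `characterize`, `annotate`, `screen` and `simulate`
subcommands.

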