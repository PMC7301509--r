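# meshsimr

Biomedical text mining constantly needs three things done with the Medical
Subject Headings (MeSH) vocabulary that indexes PubMed/MEDLINE: **recognize**
MeSH terms inside free phrases ("Graves` disease", "bardet-biedl syndrome
11"), **normalize** them onto canonical records — main headings (MHs) and the
supplementary concept records (SCRs) that cover rare diseases and specific
substances — and **compare** two terms by semantic similarity. meshsimr is an
R toolkit for all three, aimed at people curating phenotype tables (GWAS/OMIM
phenotype strings, drug indications), integrating annotations across
databases, or weighting disease terms in downstream genetic analyses.

## What it computes

The vocabulary is held in a five-table dataset (`mesh_dataset`): MH details
with dotted tree numbers, the UMLS-concept→MH map, SCR details, SCR↔MH
narrower/broader links, and the MH parent/child table. It can be built from
UMLS RRF-style pipe-delimited extracts (`build_mesh_dataset()`) or generated
synthetically with identical schema (`generate_fixture()`), so everything is
testable without licensed data.

**Information content.** With `freq(x)` the number of publications indexed by
term `x` and `N` the total indexed by MeSH,

    D(d) = {descendants of d}        (inclusive of d)
    P(d) = freq(D(d)) / N
    IC(d) = -log10 P(d)

Descendants are read off tree numbers: every heading whose tree number
properly extends one of `d`'s. A zero roll-up takes a pseudo-count of 1.

**Similarity.** Four IC-based measures driven by the most informative common
ancestor (MICA; ancestor sets are inclusive, so MICA(d,d)=d):

    Sim_res = IC(MICA)
    Sim_lin = 2 IC(MICA) / (IC(d1) + IC(d2))
    Sim_jc  = 1 - min(1, IC(d1) + IC(d2) - 2 IC(MICA))
    Sim_rel = Sim_lin * (1 - 10^(-IC(MICA)))

plus the graph-based Wang measure: each inclusive ancestor `a` of `d`
contributes `S_d(a) = omega^(edges from d to a, minimized over tree-number
paths)` with `omega = 0.6` by default, `SV_d = sum S_d`, and

    Sim_wang = sum over common ancestors of (S_d1 + S_d2) / (SV_d1 + SV_d2).

Terms whose tree numbers share no top-level category letter (e.g.
Tauopathies `C10.574.945` vs Schizophrenia `F03.700.750`) score 0 under every
measure; identical terms score 1; SCRs are replaced by their broader MHs and
the best pairing is kept, as is the best pairing across multiple tree
numbers. `mesh_similarity()` applies all of these rules; the `sim_*`
functions expose the raw per-pair formulas.

## Worked example

```r
library(meshsimr)

ds <- generate_fixture(mesh_fixture_spec(seed = 1))
ds
#> <mesh_dataset>
#>   main headings: 80
#>   SCRs:          6
#>   CUI mappings:  109
#>   parent/child:  83
#>   N_total:       207

ic <- build_ic_table(ds)
head(tidy(ic), 4)
#> # A tibble: 4 x 4
#>   ui      rollup    ic     p
#> 1 D000001    106 0.291 0.512
#> 2 D000002     39 0.725 0.188
#> 3 D000003     35 0.772 0.169
#> 4 D000004     32 0.811 0.155

tibble::tibble(ui1 = c("D000002", "D000002", "D000001"),
               ui2 = c("D000003", "D000002", "D000041")) |>
  mesh_similarity_pairs(ds, ic_table = ic)
#> # A tibble: 3 x 7
#>   ui1     ui2       res   lin     jc   rel  wang
#> 1 D000002 D000003 0.291 0.388 0.0845 0.189 0.375
#> 2 D000002 D000002 1     1     1      1     1
#> 3 D000001 D000041 0     0     0      0     0
```

The first pair are siblings: their MICA is the category root (IC 0.291), and
each measure turns that shared ancestor into a score on its own scale. The
second row is the identity boundary (always exactly 1), the third a
cross-category pair (always exactly 0).

Recognition, with SCR expansion on:

```r
parse_text(ds, "patient with condition d000004 and variant c500001",
           recognizer_config(expand_scr = TRUE))
#>   start end mesh_ui record_kind        route
#> 1    13  30 D000004          MH       direct
#> 2    35  50 C500001         SCR          scr
#> 3    35  50 D000043          MH scr_expanded
```

The SCR hit is also emitted as its broader main heading, which is what the
similarity layer compares. The same pipeline ingests MetaMap fielded (MMI)
output via `parse_mmi_output()`.

A command-line front end is installed at `exec/meshsim` with subcommands
`fixture`, `build`, `parse`, `ic` and `sim`.

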