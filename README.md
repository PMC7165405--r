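# fibrequant

Automated quantification of sarcolemmal proteins and myofibre regeneration
in multiplexed immunofluorescent images of transverse skeletal-muscle
sections — built for the dystrophin-quantification problem in Duchenne and
Becker muscular dystrophy (DMD/BMD), where trial endpoints require
objective, per-fibre measurement of membrane protein from trace to
full-intensity levels.

The package analyses three co-registered 16-bit channels: a membrane
**mask** stain (laminin α2) outlining every fibre, a **primary**
sarcolemmal stain (dystrophin), and a **tertiary** stain — either a second
sarcolemmal marker (α-sarcoglycan / β-dystroglycan, for colocalisation) or
sarcoplasmic fetal/developmental myosin (for regeneration). It segments
individual fibres from the laminin mask, partitions each into sarcolemma
ring and sarcoplasm, and quantifies staining per fibre; a synthetic-section
generator with exact ground truth validates every stage.

## The statistic at the core

Each fibre supplies its own background: the positivity threshold for a
sarcolemmal channel is

    t_i = mean(sarcoplasm_i) + k · sd(sarcoplasm_i),   k = 3

computed per fibre (no global threshold). Ring pixels above `t_i` form
8-connected positive objects, and the **Circumference Positivity** is the
percentage of the fibre's ring circumference those objects cover — by
default measured by projecting object pixels onto the ring mid-line; the
border-length form `Σ (border − 2·radial width)/2 / circumference` is
available as an alternative estimator. Fibres are classified into four
coverage bins (`0-25`, `25-50`, `50-75`, `75-100`); coverage strictly above
25% defines a protein-positive fibre. Sarcolemmal intensities are always
reported raw, without background subtraction.

## Worked example

```r
library(fibrequant)

# a synthetic section: 60 fibres at four coverage levels, realistic noise
spec <- section_spec(n_fibres = 60,
                     primary_coverage_fractions = rep(c(0.05, 0.3, 0.6, 0.95), 15),
                     seed = 2024)
sec <- generate_section(spec)

an <- analyse_section(sec$stack)
an$summary
#> section_summary: 60 fibres analysed (0 unquantifiable, 0 rejected)
#>   % positive (> 25% coverage): 75.0
#>   mean sarcolemmal intensity: 18446 AU
#>   coverage classes (0-25/25-50/50-75/75-100): 15/15/15/15
```

The four painted coverage levels (5%, 30%, 60%, 95% of the ring) are
recovered as 15 fibres in each class, and the 45 fibres above the 25%
cutoff give 75% positivity. Per-fibre records carry morphometrics and the
staining profile:

```r
head(an$records[, c("label", "fibre_area", "primary_threshold",
                    "primary_circumference_positivity", "primary_coverage_class")])
#>   label fibre_area primary_threshold primary_circumference_positivity primary_coverage_class
#> 1     1    2313.00          9470.319                         5.469036                   0-25
#> 2     2    1694.75          9502.153                         5.239170                   0-25
#> 3     3    1845.75          9501.957                         5.498240                   0-25
```

(the first fibres were painted at 5% coverage; each threshold is that
fibre's own `mean + 3·sd` of its sarcoplasm, ≈ 8000 + 3·500 AU). Use
`write_section_outputs(an, "out/")` for the per-fibre CSV, summary JSON,
rejected-candidate log and classification-map PNG, and
`inst/cli/fibrequant.R` for a shell interface (`simulate`, `run`,
`myosin-threshold`, `compare-replicates`).

For regeneration analysis, derive the myosin threshold from negative
controls, then classify test sections against it:

```r
controls <- generate_control_panel(
  section_spec(n_fibres = 64, tertiary_mode = "sarcoplasmic", seed = 1), 5)
thr <- derive_myosin_threshold(
  lapply(controls, function(s) analyse_section(s$stack)$records))
analyse_section(test_stack, myosin_threshold = thr)$summary$pct_myosin_positive
```

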