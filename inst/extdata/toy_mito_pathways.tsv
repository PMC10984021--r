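pathway	gene
OxPhos_CI	OxPhos_CI_g01
OxPhos_CI	OxPhos_CI_g02
OxPhos_CI	OxPhos_CI_g03
OxPhos_CI	OxPhos_CI_g04
OxPhos_CI	OxPhos_CI_g05
OxPhos_CI	OxPhos_CI_g06
OxPhos_CI	OxPhos_CI_g07
OxPhos_CI	OxPhos_CI_g08
OxPhos_CI	OxPhos_CI_g09
OxPhos_CI	OxPhos_CI_g10
OxPhos_CI	OxPhos_CI_g11
OxPhos_CI	OxPhos_CI_g12
OxPhos_CI	OxPhos_CI_g13
OxPhos_CI	OxPhos_CI_g14
OxPhos_CI	OxPhos_CI_g15
OxPhos_CII	OxPhos_CII_g01
OxPhos_CII	OxPhos_CII_g02
OxPhos_CII	OxPhos_CII_g03
OxPhos_CII	OxPhos_CII_g04
OxPhos_CII	OxPhos_CII_g05
OxPhos_CII	OxPhos_CII_g06
OxPhos_CII	OxPhos_CII_g07
OxPhos_CII	OxPhos_CII_g08
OxPhos_CII	OxPhos_CII_g09
OxPhos_CII	OxPhos_CII_g10
OxPhos_CII	OxPhos_CII_g11
OxPhos_CII	OxPhos_CII_g12
OxPhos_CII	OxPhos_CII_g13
OxPhos_CII	OxPhos_CII_g14
OxPhos_CII	OxPhos_CII_g15
OxPhos_CIII	OxPhos_CIII_g01
OxPhos_CIII	OxPhos_CIII_g02
OxPhos_CIII	OxPhos_CIII_g03
OxPhos_CIII	OxPhos_CIII_g04
OxPhos_CIII	OxPhos_CIII_g05
OxPhos_CIII	OxPhos_CIII_g06
OxPhos_CIII	OxPhos_CIII_g07
OxPhos_CIII	OxPhos_CIII_g08
OxPhos_CIII	OxPhos_CIII_g09
OxPhos_CIII	OxPhos_CIII_g10
OxPhos_CIII	OxPhos_CIII_g11
OxPhos_CIII	OxPhos_CIII_g12
OxPhos_CIII	OxPhos_CIII_g13
OxPhos_CIII	OxPhos_CIII_g14
OxPhos_CIII	OxPhos_CIII_g15
OxPhos_CIV	OxPhos_CIV_g01
OxPhos_CIV	OxPhos_CIV_g02
OxPhos_CIV	OxPhos_CIV_g03
OxPhos_CIV	OxPhos_CIV_g04
OxPhos_CIV	OxPhos_CIV_g05
OxPhos_CIV	OxPhos_CIV_g06
OxPhos_CIV	OxPhos_CIV_g07
OxPhos_CIV	OxPhos_CIV_g08
OxPhos_CIV	OxPhos_CIV_g09
OxPhos_CIV	OxPhos_CIV_g10
OxPhos_CIV	OxPhos_CIV_g11
OxPhos_CIV	OxPhos_CIV_g12
OxPhos_CIV	OxPhos_CIV_g13
OxPhos_CIV	OxPhos_CIV_g14
OxPhos_CIV	OxPhos_CIV_g15
ATP_synthase	ATP_synthase_g01
ATP_synthase	ATP_synthase_g02
ATP_synthase	ATP_synthase_g03
ATP_synthase	ATP_synthase_g04
ATP_synthase	ATP_synthase_g05
ATP_synthase	ATP_synthase_g06
ATP_synthase	ATP_synthase_g07
ATP_synthase	ATP_synthase_g08
ATP_synthase	ATP_synthase_g09
ATP_synthase	ATP_synthase_g10
ATP_synthase	ATP_synthase_g11
ATP_synthase	ATP_synthase_g12
ATP_synthase	ATP_synthase_g13
ATP_synthase	ATP_synthase_g14
ATP_synthase	ATP_synthase_g15
TCA_cycle	TCA_cycle_g01
TCA_cycle	TCA_cycle_g02
TCA_cycle	TCA_cycle_g03
TCA_cycle	TCA_cycle_g04
TCA_cycle	TCA_cycle_g05
TCA_cycle	TCA_cycle_g06
TCA_cycle	TCA_cycle_g07
TCA_cycle	TCA_cycle_g08
TCA_cycle	TCA_cycle_g09
TCA_cycle	TCA_cycle_g10
TCA_cycle	TCA_cycle_g11
TCA_cycle	TCA_cycle_g12
TCA_cycle	TCA_cycle_g13
TCA_cycle	TCA_cycle_g14
TCA_cycle	TCA_cycle_g15
FA_oxidation	FA_oxidation_g01
FA_oxidation	FA_oxidation_g02
FA_oxidation	FA_oxidation_g03
FA_oxidation	FA_oxidation_g04
FA_oxidation	FA_oxidation_g05
FA_oxidation	FA_oxidation_g06
FA_oxidation	FA_oxidation_g07
FA_oxidation	FA_oxidation_g08
FA_oxidation	FA_oxidation_g09
FA_oxidation	FA_oxidation_g10
FA_oxidation	FA_oxidation_g11
FA_oxidation	FA_oxidation_g12
FA_oxidation	FA_oxidation_g13
FA_oxidation	FA_oxidation_g14
FA_oxidation	FA_oxidation_g15
Mito_dynamics	Mito_dynamics_g01
Mito_dynamics	Mito_dynamics_g02
Mito_dynamics	Mito_dynamics_g03
Mito_dynamics	Mito_dynamics_g04
Mito_dynamics	Mito_dynamics_g05
Mito_dynamics	Mito_dynamics_g06
Mito_dynamics	Mito_dynamics_g07
Mito_dynamics	Mito_dynamics_g08
Mito_dynamics	Mito_dynamics_g09
Mito_dynamics	Mito_dynamics_g10
Mito_dynamics	Mito_dynamics_g11
Mito_dynamics	Mito_dynamics_g12
Mito_dynamics	Mito_dynamics_g13
Mito_dynamics	Mito_dynamics_g14
Mito_dynamics	Mito_dynamics_g15
mtDNA_maintenance	mtDNA_maintenance_g01
mtDNA_maintenance	mtDNA_maintenance_g02
mtDNA_maintenance	mtDNA_maintenance_g03
mtDNA_maintenance	mtDNA_maintenance_g04
mtDNA_maintenance	mtDNA_maintenance_g05
mtDNA_maintenance	mtDNA_maintenance_g06
mtDNA_maintenance	mtDNA_maintenance_g07
mtDNA_maintenance	mtDNA_maintenance_g08
mtDNA_maintenance	mtDNA_maintenance_g09
mtDNA_maintenance	mtDNA_maintenance_g10
mtDNA_maintenance	mtDNA_maintenance_g11
mtDNA_maintenance	mtDNA_maintenance_g12
mtDNA_maintenance	mtDNA_maintenance_g13
mtDNA_maintenance	mtDNA_maintenance_g14
mtDNA_maintenance	mtDNA_maintenance_g15
Protein_import	Protein_import_g01
Protein_import	Protein_import_g02
Protein_import	Protein_import_g03
Protein_import	Protein_import_g04
Protein_import	Protein_import_g05
Protein_import	Protein_import_g06
Protein_import	Protein_import_g07
Protein_import	Protein_import_g08
Protein_import	Protein_import_g09
Protein_import	Protein_import_g10
Protein_import	Protein_import_g11
Protein_import	Protein_import_g12
Protein_import	Protein_import_g13
Protein_import	Protein_import_g14
Protein_import	Protein_import_g15
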