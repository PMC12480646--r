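ref_id	class	order	family	genus	species
ref_dreissena_rostriformis	Bivalvia	Myida	Dreissenidae	Dreissena	Dreissena rostriformis
ref_dreissena_polymorpha	Bivalvia	Myida	Dreissenidae	Dreissena	Dreissena polymorpha
ref_lasmigona_costata	Bivalvia	Unionida	Unionidae	Lasmigona	Lasmigona costata
ref_micropterus_nigricans	Actinopteri	Centrarchiformes	Centrarchidae	Micropterus	Micropterus nigricans
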