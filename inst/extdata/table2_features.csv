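name,kind,start,end,strand,note
rluF,other,245,2109,+,ribosomal large subunit pseudouridine synthase F homolog
Pol,other,3536,4072,+,DNA/RNA polymerase homolog
Pol,other,5603,6601,+,reverse transcriptase-RNase H-integrase homolog
hyp1,other,9893,10651,+,conserved hypothetical protein
CYP,other,13695,15784,+,cytochrome P450 homolog
omt,other,16301,23699,+,O-methyltransferase homolog
rnt,other,24383,25349,+,ribonuclease T homolog
PEphb3.1,pheromone,26325,26510,+,mating-type peptide pheromone precursor
PEphb3.2,pheromone,27056,27232,+,mating-type peptide pheromone precursor
PESTE3.3.1,receptor,28186,29384,+,STE3-class pheromone receptor
PEphb3.3,pheromone,29629,29877,+,mating-type peptide pheromone precursor
PESTE3.3.2,receptor,30416,31911,+,STE3-class pheromone receptor
PESTE3.3.3,receptor,32405,34232,+,STE3-class pheromone receptor
PEphb3.4,pheromone,35693,35869,+,mating-type peptide pheromone precursor
PESTE3.3.4,receptor,36579,38224,+,STE3-class pheromone receptor
hyp2,other,38948,41569,+,hypothetical protein
ubiA,other,43157,43972,+,UbiA prenyltransferase homolog
hyp3,other,44187,45557,+,predicted protein
sgnH,other,46375,48010,+,SGNH hydrolase homolog
hyp4,other,48339,51782,+,hypothetical protein
hyp5,other,53063,55751,+,hypothetical protein
Pol,other,57385,59974,+,reverse transcriptase-RNase H-integrase homolog
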