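[
  {
    "anchor_id": "box1_q1",
    "source": "FDA Warning Letter, CBD/COVID-19 misinformation quote",
    "text": "Firstly, the research performed to date has shown that CBD can reduce a number of pro-inflammatory cytokines (numerous different types of substances, such as interferon, interleukin, and growth factors, which are secreted by certain cells of the immune system and have an effect on other cells) including IL-6, the one reduced by other drugs being studied for COVID-19. CBD was also shown to reduce interleukin (IL)-2, IL-1α and β, interferon gamma, inducible protein-10, monocyte chemoattractant protein-1, macrophage inflammatory protein-1α, and tumor necrosis factor-α – all of which are associated with the pathology of severe cases of COVID-19. In addition to reducing these pro-inflammatory cytokines, CBD has also been shown to increase the production of interferons, a type of signaling protein that activates immune cells and prevents viruses from replicating"
  },
  {
    "anchor_id": "box1_q2",
    "source": "FDA Warning Letter, CBD/COVID-19 misinformation quote",
    "text": "There has been an increased interest in CBD and Covid-19 to treat lung problems and symptoms (mental or physical) associated with the coronavirus"
  },
  {
    "anchor_id": "box1_q3",
    "source": "FDA Warning Letter, CBD/COVID-19 misinformation quote",
    "text": "CBD oil may help to prevent getting infected by strengthening your immune system. It has also been proven to offer relief to some of the symptoms"
  },
  {
    "anchor_id": "box1_q4",
    "source": "FDA Warning Letter, CBD/COVID-19 misinformation quote",
    "text": "By using CBD oil, you can keep inflammation at bay, retain a healthy or even higher than average white blood cell count, stay calm and relaxed (which is best for a strong immune system), and prevent catching a virus or infection beforehand"
  },
  {
    "anchor_id": "box1_q5",
    "source": "FDA Warning Letter, CBD/COVID-19 misinformation quote",
    "text": "Is CBD an Anti-Viral Agent for Coronavirus, Influenza, MERS, and Sars Plus Key Antiviral Supplements?"
  },
  {
    "anchor_id": "statement_03",
    "source": "FDA Warning Letter, CBD/COVID-19 statement 3",
    "text": "Firstly, the research performed to date has shown that CBD can reduce a number of pro-inflammatory cytokines (numerous different types of substances, such as interferon, interleukin, and growth factors, which are secreted by certain cells of the immune system and have an effect on other cells) including IL-6, the one reduced by other drugs being studied for COVID-19. CBD was also shown to reduce interleukin (IL)-2, IL-1α and β, interferon gamma, inducible protein-10, monocyte chemoattractant protein-1, macrophage inflammatory protein-1α, and tumor necrosis factor-α – all of which are associated with the pathology of severe cases of COVID-19. In addition to reducing these pro-inflammatory cytokines, CBD has also been shown to increase the production of interferons, a type of signaling protein that activates immune cells and prevents viruses from replicating"
  },
  {
    "anchor_id": "statement_08",
    "source": "FDA Warning Letter, CBD/COVID-19 statement 8",
    "text": "DML CBD: Immune Boost Pack... ALERT: There is no cure or treatment for COVID19. With this in mind, many doctors claim the best defense is to boost the body’s immune system. DML CBD aims to help our customers in an attempt to boost the immune system... WHY TO BUY THE BOOST PACK: Studies suggest that CBD can help fight off inflammation, boost the immune system, and help battle against certain harmful bacteria. Some research suggests it can help suppress the cytokine storm inside the body that can cause great illness and sometimes death... NOTE: The cytokine storm is often triggered in patients with COVID19. Please note there is no proven cure or treatment for COVID19... There has never been a more important time than to boost your immune system. To help our customers get a full CBD experience that aims to boost your immune system, we offer the ‘DML CBD Immune Boost’ package..."
  },
  {
    "anchor_id": "statement_12a",
    "source": "FDA Warning Letter, CBD/COVID-19 statement 12",
    "text": "What is COVID-19? Coronavirus is referred to as a novel cause for viral pneumonia because it’s a virus we haven’t seen before and have developed no immunity to... What Happens If You Get Infected and What Can Help? ...Regardless of the shape you’re in at this moment, there may be ways you can prepare and protect your body from developing a more severe response to infection. Explore the solutions included in NoronaPak below! [graphic with the following text] ‘Selenium, Cannabidiol (CBD), Vitamin-C, Zinc, Vitamin-D, N-Acetylcysteine’... Supplementation with selenium results in changes in the gene expression that is required for protein biosynthesis in lymphocytes, the infection-fighting cells that are crucial to the immune system being able to identify infection and mount an immune response... Selenium is not only important in boosting the immunity of the individual but also to slow the development of more virulent strains of some viral pathogens... CBD may suppress the productions of cytokines in the setting of infection"
  },
  {
    "anchor_id": "statement_12b",
    "source": "FDA Warning Letter, CBD/COVID-19 statement 12",
    "text": "In the wake of the current epidemic, it is now more important than ever to keep your immune system as healthy as can be... Here are 5 key ways to strengthen your immune system during the outbreak...Take supplements such as CBD"
  },
  {
    "anchor_id": "statement_26",
    "source": "FDA Warning Letter, CBD/COVID-19 statement 26",
    "text": "Crush Corona... While scientists around the world are working 24/7 to develop a COVID-19 vaccine, it will take many more months of testing before it’s approved and available. However, there’s something you can do right now to strengthen your immune system. Take CBD... CBD can help keep your immune system at the stop of its game... We want everyone to take CBD and take advantage of its potential to help prepare your body to fight a coronavirus infection. So, we’re making all of our products more affordable"
  }
]
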